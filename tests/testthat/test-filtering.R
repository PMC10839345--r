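test_that("phantom reads are zeroed per pair and phantom-only ASVs dropped", {
  # pair 1: ASV x phantom (DNA=0, RNA=5); pair 2: x real (DNA=7, RNA=2)
  dna <- rbind(c(0L, 3L), c(7L, 3L))
  rna <- rbind(c(5L, 1L), c(2L, 1L))
  colnames(dna) <- colnames(rna) <- c("x", "y")
  ds <- pairedSet(dna, rna, subjects = c("B1", "B2"))
  out <- removePhantomReads(ds)
  rnaM <- counts(rnaCounts(out$dataset))
  expect_equal(unname(rnaM[1, "x"]), 0L)   # zeroed where DNA = 0
  expect_equal(unname(rnaM[2, "x"]), 2L)   # retained where DNA > 0
  expect_equal(out$report@readsRemoved[["rna"]], 5)

  # ASV phantom in every pair and absent from DNA vanishes entirely
  dna2 <- cbind(dna, z = c(0L, 0L))
  rna2 <- cbind(rna, z = c(4L, 4L))
  ds2 <- pairedSet(dna2, rna2, subjects = c("B1", "B2"))
  out2 <- removePhantomReads(ds2)
  expect_false("z" %in% asvIDs(out2$dataset))
  expect_equal(out2$report@asvsRemoved, "z")

  # already nested supports: identity
  ds3 <- pairedSet(rbind(c(5L, 2L)), rbind(c(1L, 0L)))
  out3 <- removePhantomReads(ds3)
  expect_identical(counts(rnaCounts(out3$dataset)), counts(rnaCounts(ds3)))
})

test_that("global phantom scope only drops ASVs absent from every DNA sample", {
  dna <- rbind(c(0L, 3L), c(7L, 3L))
  rna <- rbind(c(5L, 1L), c(2L, 1L))
  colnames(dna) <- colnames(rna) <- c("x", "y")
  ds <- pairedSet(dna, rna, subjects = c("B1", "B2"))
  out <- removePhantomReads(ds, scope = "global")
  # x has DNA support in pair 2, so its RNA counts survive everywhere
  expect_equal(unname(counts(rnaCounts(out$dataset))[1, "x"]), 5L)
})

test_that("abundance screen uses >= on per-sample proportions and is idempotent", {
  # sample totals 1000: a count of 10 is exactly 1 percent -> kept; 9 -> dropped
  dna <- rbind(c(10L, 9L, 981L))
  rna <- rbind(c(10L, 9L, 981L))
  colnames(dna) <- colnames(rna) <- c("keep", "drop", "bulk")
  ds <- pairedSet(dna, rna)
  out <- abundanceFilter(ds, threshold = 0.01)
  expect_setequal(asvIDs(out$dataset), c("keep", "bulk"))
  expect_equal(out$report@asvsRemoved, "drop")

  # single-ASV table: proportion 1, kept
  ds1 <- pairedSet(rbind(5L), rbind(3L))
  expect_equal(nASVs(abundanceFilter(ds1)$dataset), 1)

  # idempotence on random tables
  for (seed in 1:20) {
    ds <- randomPairedSet(seed)
    once <- abundanceFilter(ds, 0.05)$dataset
    twice <- abundanceFilter(once, 0.05)$dataset
    expect_identical(counts(dnaCounts(twice)), counts(dnaCounts(once)))
    expect_identical(counts(rnaCounts(twice)), counts(rnaCounts(once)))
  }
})

test_that("rarefaction draws exactly depth reads without replacement, reproducibly", {
  set.seed(1)
  m <- matrix(rpois(5 * 30, 20), 5, 30,
              dimnames = list(paste0("s", 1:5), paste0("a", 1:30)))
  tab <- CountTable(m)
  r1 <- rarefyCounts(tab, 100, seed = 99)
  r2 <- rarefyCounts(tab, 100, seed = 99)
  expect_identical(counts(r1), counts(r2))            # bit-identical rerun
  expect_true(all(rowSums(counts(r1)) == 100))        # exact depth
  expect_true(all(counts(r1) <= counts(tab)))         # without replacement

  # depth equal to a sample's total leaves the row unchanged
  tot <- rowSums(m)
  rFull <- rarefyCounts(tab[1, ], depth = tot[1], seed = 5)
  expect_identical(counts(rFull), counts(tab[1, ]))

  # shallow samples error by name, or drop under the flag
  expect_error(rarefyCounts(tab, max(tot) + 1, seed = 1), "s1")
  expect_warning(r <- rarefyCounts(tab, max(tot), seed = 1, dropShallow = TRUE),
                 "dropping")
  expect_lt(nSamples(r), 5)
})

test_that("rarefied counts match the hypergeometric expectation", {
  x <- matrix(c(30L, 70L), 1, 2, dimnames = list("s", c("a", "b")))
  tab <- CountTable(x)
  depth <- 50
  draws <- vapply(1:1000, function(s)
    counts(rarefyCounts(tab, depth, seed = s))[1, "a"], numeric(1))
  expected <- depth * 30 / 100
  hypVar <- depth * 0.3 * 0.7 * (100 - depth) / 99
  se <- sqrt(hypVar / 1000)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("pseudocount adjustment eliminates RNA>0/DNA=0 cells", {
  dna <- rbind(c(0L, 10L, 4L))
  rna <- rbind(c(3L, 2L, 0L))
  ds <- pairedSet(dna, rna)
  adj <- pseudocountAdjust(ds)                        # literal "any value" mode
  d <- counts(dnaCounts(adj))[1, ]
  expect_equal(unname(d), c(1L, 11L, 4L))             # +1 wherever RNA > 0
  expect_identical(counts(rnaCounts(adj)), counts(rnaCounts(ds)))

  adjZ <- pseudocountAdjust(ds, mode = "zeros")       # only DNA = 0 cells
  expect_equal(unname(counts(dnaCounts(adjZ))[1, ]), c(1L, 10L, 4L))

  # RNA = 0 everywhere: identity
  dsQuiet <- pairedSet(rbind(c(5L, 2L)), rbind(c(0L, 0L)))
  expect_identical(counts(dnaCounts(pseudocountAdjust(dsQuiet))),
                   counts(dnaCounts(dsQuiet)))

  # adds exactly #(RNA > 0) reads to the DNA total
  for (seed in 1:10) {
    ds <- randomPairedSet(seed)
    adj <- pseudocountAdjust(ds)
    expect_equal(sum(counts(dnaCounts(adj))) - sum(counts(dnaCounts(ds))),
                 sum(counts(rnaCounts(ds)) > 0))
  }
})
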