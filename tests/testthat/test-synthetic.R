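fastCfg <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 3, n_control = 1, n_asvs = 100,
         dna_depth_range = c(2000, 3000),
         rna_depth_range = c(2500, 3500), seed = 5),
    list(...))
  do.call(scenarioConfig, args)
}

test_that("truth generation is deterministic and honours the role fractions", {
  cfg <- fastCfg()
  t1 <- generateTruth(cfg)
  t2 <- generateTruth(cfg)
  expect_identical(t1, t2)
  expect_equal(names(t1), paste0("S", 1:3))

  # transient implies no living cells; all abundances finite, non-negative
  tr <- t1$S1
  expect_true(all(tr$living_abundance[tr$transient] == 0))
  expect_true(all(tr$living_abundance >= 0 & is.finite(tr$living_abundance)))
  expect_true(all(tr$relic_abundance >= 0 & is.finite(tr$relic_abundance)))

  # no dead-only, no transient -> every ASV lives
  allLive <- generateTruth(fastCfg(frac_dead = 0, frac_transient = 0))
  expect_true(all(allLive$S1$living_abundance > 0))

  # realized dead fraction within binomial error at 1000 ASVs
  big <- generateTruth(scenarioConfig(n_subjects = 1, n_control = 0,
                                      n_asvs = 1000, frac_dead = 0.55,
                                      frac_transient = 0, seed = 77))
  dead <- with(big$S1, living_abundance == 0 & !transient)
  se <- sqrt(0.55 * 0.45 / 1000)
  expect_lt(abs(mean(dead) - 0.55), 4 * se)
})

test_that("sampled counts follow the generative probabilities", {
  cfg <- fastCfg(frac_dead = 0.3, frac_transient = 0.1)
  truth <- generateTruth(cfg)$S1

  # dead taxa are silent in RNA, always
  sim <- simulatePair(truth, 5000, 5000, seed = 3)
  expect_true(all(sim$rna[truth$living_abundance == 0] == 0L))
  expect_identical(simulatePair(truth, 5000, 5000, seed = 3), sim)

  # model collapse: no relic, no transients, full activity, unit factors
  cfg0 <- fastCfg(frac_dead = 0, frac_transient = 0, frac_dormant = 0,
                  a_hi = 1, rrna_factor = 1, gene_copies = 1)
  tr0 <- generateTruth(cfg0)$S1
  expect_equal(expectedReadProportions(tr0, "DNA"),
               expectedReadProportions(tr0, "RNA"))

  # multinomial concentration at depth 1e5: within 3 binomial SEs
  pD <- expectedReadProportions(truth, "DNA")
  simBig <- simulatePair(truth, 1e5, 1e5, seed = 9)
  obs <- simBig$dna / 1e5
  se <- sqrt(pD * (1 - pD) / 1e5)
  frac <- mean(abs(obs - pD) <= 3 * se + 1e-12)
  expect_gt(frac, 0.95)
})

test_that("treatment semantics: bacteriostatic scales activity, bactericidal abundance", {
  truth <- generateTruth(fastCfg(frac_susceptible = 1, frac_dormant = 0,
                                 a_hi = 0.8))$S1
  same <- applyTreatment(truth, f = 1)
  expect_identical(same, truth)

  hit <- applyTreatment(truth, f = 0.1)
  liv <- truth$living_abundance > 0
  expect_equal(hit$activity[liv], rep(0.08, sum(liv)))
  expect_equal(hit$living_abundance, truth$living_abundance)

  kill <- applyTreatment(truth, f = 0.1, mode = "bactericidal")
  expect_equal(kill$living_abundance[liv], truth$living_abundance[liv] * 0.1)
  expect_equal(kill$activity, truth$activity)

  # compositional blindness: uniform susceptibility + equal rRNA factors
  # leave expected RNA proportions exactly unchanged
  expect_equal(expectedReadProportions(hit, "RNA"),
               expectedReadProportions(truth, "RNA"))
  # ...but heterogeneous susceptibility shifts them
  het <- truth
  het$susceptible[seq_len(nrow(het)) %% 2 == 0] <- FALSE
  hetHit <- applyTreatment(het, f = 0.1)
  expect_gt(max(abs(expectedReadProportions(hetHit, "RNA") -
                      expectedReadProportions(het, "RNA"))), 1e-4)
})

test_that("a generated study mirrors the paired two-arm design, reproducibly", {
  cfg <- fastCfg()
  study <- generateStudy(cfg)
  ds <- study$dataset
  expect_s4_class(ds, "PairedAmpliconSet")
  p <- samplePairs(ds)
  expect_equal(nrow(p), 6)                      # 3 subjects x 2 timepoints
  expect_equal(nSamples(dnaCounts(ds)) + nSamples(rnaCounts(ds)), 12)
  expect_equal(sum(p$treatment == "control" & p$timepoint == "post"), 1)
  expect_equal(sum(p$treatment == "antibiotic" & p$timepoint == "post"), 2)

  # truth sidecar covers every subject/timepoint with labels tests consume
  expect_setequal(unique(study$truth$timepoint), c("pre", "post"))
  expect_true(all(c("living_abundance", "relic_abundance", "activity",
                    "susceptible", "transient") %in% names(study$truth)))

  # same config + seed: identical; different seed: different
  study2 <- generateStudy(cfg)
  expect_identical(counts(dnaCounts(study2$dataset)), counts(dnaCounts(ds)))
  study3 <- generateStudy(fastCfg(seed = 6))
  expect_false(identical(counts(dnaCounts(study3$dataset)),
                         counts(dnaCounts(ds))))

  # default design: 7 subjects, 3 control / 4 antibiotic, 14 swab events
  def <- scenarioConfig()
  expect_equal(def$n_subjects, 7L)
  expect_equal(def$n_control, 3L)
  expect_equal(def$dna_depth_range, c(19821L, 58962L))
  expect_equal(def$rna_depth_range, c(28721L, 83021L))
})

test_that("study files round-trip through the TSV dialect", {
  study <- generateStudy(fastCfg(n_asvs = 40))
  dir <- withr::local_tempdir()
  writeStudy(study, dir)
  expect_true(all(file.exists(file.path(dir,
    c("dna_counts.tsv", "rna_counts.tsv", "metadata.tsv",
      "truth.tsv", "scenario.yaml")))))
  dna <- readCountTable(file.path(dir, "dna_counts.tsv"))
  rna <- readCountTable(file.path(dir, "rna_counts.tsv"))
  meta <- readSampleMetadata(file.path(dir, "metadata.tsv"))
  ds <- buildPairedDataset(dna, rna, meta)
  expect_identical(counts(dnaCounts(ds)), counts(dnaCounts(study$dataset)))

  expect_error(scenarioConfig(frac_dead = 0.7, frac_transient = 0.5),
               "exceeds 1")
  expect_error(scenarioConfig(treatment_f = 0), "treatment_f")
})
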