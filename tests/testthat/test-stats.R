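test_that("Kruskal-Wallis H matches the rank-sum formula and is label-invariant", {
  r <- kruskalWallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # H = 12/(n(n+1)) * sum(R_j^2 / n_j) - 3(n+1), ranks untied
  expect_equal(r$statistic, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7,
               tolerance = 1e-10)
  expect_equal(r$statistic, 3.857142857, tolerance = 1e-6)
  expect_equal(r$df, 1)

  # permuting observation order leaves the result unchanged
  set.seed(1)
  v <- rnorm(12); g <- rep(c("a", "b", "c"), 4)
  o <- sample(12)
  expect_equal(kruskalWallis(v, g), kruskalWallis(v[o], g[o]))

  # complete ties carry no evidence
  tied <- kruskalWallis(rep(2.5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_raw, 1)

  expect_error(kruskalWallis(1:3, rep("a", 3)), "2 non-empty groups")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)           # single p unchanged
  expect_equal(bhAdjust(c(1, 1, 1)), rep(1, 3))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(2024)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    expect_equal(bhAdjust(p), bhBruteForce(p), tolerance = 1e-12)
  }
})

test_that("PERMANOVA decomposes variance and matches full enumeration", {
  # two well-separated clusters of 3
  set.seed(9)
  pts <- rbind(matrix(rnorm(9, 0), 3), matrix(rnorm(9, 30), 3))
  rownames(pts) <- paste0("s", 1:6)
  dm <- dist(pts)
  g <- rep(c("lo", "hi"), each = 3)
  r <- permanova(dm, groups = g, permutations = 999, seed = 1)
  expect_gt(r$statistic, 50)
  # minimal achievable p: only the original split (either orientation)
  # reaches this F, i.e. 2 * 3! * 3! of 720 relabelings
  pExact <- permanovaExactP(as.matrix(dm), g)
  expect_equal(pExact, 0.1, tolerance = 1e-10)
  expect_equal(r$p_raw, pExact, tolerance = 0.05)
  # the hand-rolled pseudo-F agrees with the implementation's
  expect_equal(r$statistic, pseudoF(as.matrix(dm), g), tolerance = 1e-8)

  # R^2 of all terms plus residual sums to 1 (single factor: term + residual)
  set.seed(10)
  pts2 <- matrix(rnorm(24), 8, 3); rownames(pts2) <- paste0("s", 1:8)
  dm2 <- dist(pts2)
  g2 <- rep(c("a", "b"), 4)
  r2 <- permanova(dm2, groups = g2, permutations = 99, seed = 2)
  # recompute residual share from the decomposition identity
  ssT <- sum(as.matrix(dm2)[upper.tri(as.matrix(dm2))]^2) / 8
  expect_equal(r2$r_squared, (pseudoF(as.matrix(dm2), g2) / 6) /
                 (1 + pseudoF(as.matrix(dm2), g2) / 6), tolerance = 1e-8)

  # structureless matrix: permutation p within Monte-Carlo error of exact
  set.seed(11)
  pts3 <- matrix(rnorm(18), 6, 3); rownames(pts3) <- paste0("s", 1:6)
  dm3 <- dist(pts3)
  g3 <- rep(c("a", "b"), each = 3)
  pEx <- permanovaExactP(as.matrix(dm3), g3)
  r3 <- permanova(dm3, groups = g3, permutations = 999, seed = 3)
  expect_lt(abs(r3$p_raw - pEx), 0.06)

  expect_error(permanova(dm, groups = c("a", rep("b", 5))), "singleton")
})

test_that("beta dispersion test separates spread from location", {
  set.seed(12)
  tight <- matrix(rnorm(30, sd = 0.05), 10, 3)
  loose <- matrix(rnorm(30, sd = 5), 10, 3)
  pts <- rbind(tight, loose); rownames(pts) <- paste0("s", 1:20)
  g <- rep(c("tight", "loose"), each = 10)
  r <- betaDispersionTest(dist(pts), g, permutations = 999, seed = 4)
  expect_lt(r$p_raw, 0.01)

  # mirror-image groups have equal dispersion
  set.seed(13)
  a <- matrix(rnorm(30), 10, 3)
  pts2 <- rbind(a, -a); rownames(pts2) <- paste0("s", 1:20)
  r2 <- betaDispersionTest(dist(pts2), g, permutations = 999, seed = 5)
  expect_gt(r2$p_raw, 0.2)

  expect_error(betaDispersionTest(dist(a), rep("one", 10)), "2 groups")
})

test_that("pairwise PERMANOVAs cover every pair and find the separated group", {
  set.seed(14)
  A <- matrix(rnorm(12, 0), 4); B <- matrix(rnorm(12, 0.2), 4)
  C <- matrix(rnorm(12, 40), 4)
  pts <- rbind(A, B, C); rownames(pts) <- paste0("s", 1:12)
  g <- rep(c("A", "B", "C"), each = 4)
  r <- pairwisePermanova(dist(pts), g, permutations = 999, seed = 6)
  expect_equal(nrow(r), 3)                     # k(k-1)/2
  pAB <- r$p_adjusted[r$group1 == "A" & r$group2 == "B"]
  pAC <- r$p_adjusted[r$group1 == "A" & r$group2 == "C"]
  pBC <- r$p_adjusted[r$group1 == "B" & r$group2 == "C"]
  expect_gt(pAB, 0.2)
  expect_lt(pAC, 0.06)
  expect_lt(pBC, 0.06)

  # three draws from one distribution: nothing significant
  set.seed(15)
  pts0 <- matrix(rnorm(36), 12, 3); rownames(pts0) <- paste0("s", 1:12)
  r0 <- pairwisePermanova(dist(pts0), g, permutations = 499, seed = 7)
  expect_true(all(r0$p_adjusted > 0.1))
})

test_that("Mantel r and permutation p match the enumeration oracle", {
  set.seed(16)
  pts <- matrix(rnorm(10), 5, 2); rownames(pts) <- paste0("s", 1:5)
  dm1 <- dist(pts)
  expect_equal(mantelTest(dm1, dm1, 99, seed = 1)$statistic, 1)

  # positive affine transform leaves r at exactly 1
  dm3 <- 0.3 * dm1 + 2
  expect_equal(mantelTest(dm1, dm3, 99, seed = 2)$statistic, 1)

  # against an independent matrix: p agrees with all-120-relabelings oracle
  set.seed(17)
  pts2 <- matrix(rnorm(10), 5, 2); rownames(pts2) <- paste0("s", 1:5)
  dm2 <- dist(pts2)
  ex <- mantelExact(as.matrix(dm1), as.matrix(dm2))
  mt <- mantelTest(dm1, dm2, permutations = 999, seed = 3)
  expect_equal(mt$statistic, ex$r, tolerance = 1e-10)
  expect_lt(abs(mt$p_raw - ex$p), 3 * sqrt(ex$p * (1 - ex$p) / 999) + 2e-3)

  # label mismatch is refused
  dmX <- dm2; attr(dmX, "Labels") <- paste0("t", 1:5)
  expect_error(mantelTest(dm1, dmX), "identical labels")
})

test_that("permutation tests are bit-reproducible under a seed", {
  set.seed(18)
  pts <- matrix(rnorm(24), 8, 3); rownames(pts) <- paste0("s", 1:8)
  dm <- dist(pts)
  g <- rep(c("a", "b"), each = 4)
  expect_identical(permanova(dm, groups = g, permutations = 199, seed = 42),
                   permanova(dm, groups = g, permutations = 199, seed = 42))
  pts2 <- matrix(rnorm(24), 8, 3); rownames(pts2) <- paste0("s", 1:8)
  expect_identical(mantelTest(dm, dist(pts2), 199, seed = 42),
                   mantelTest(dm, dist(pts2), 199, seed = 42))
})
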