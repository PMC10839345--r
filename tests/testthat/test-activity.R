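adjustedSet <- function(dna, rna, ...) {
  pseudocountAdjust(pairedSet(dna, rna, ...))
}

test_that("RNA:DNA ratios follow the pseudocount arithmetic with absence flagged", {
  # DNA after adjustment: (0+1, 8, 7, 0) for RNA (3, 8, 0, 0)
  ds <- adjustedSet(rbind(c(0L, 8L, 7L, 0L)), rbind(c(3L, 8L, 0L, 0L)))
  rm <- rnaDnaRatio(ds)
  r <- ratios(rm)[1, ]
  expect_equal(unname(r[1]), 3)        # RNA=3 over adjusted DNA=1
  expect_equal(unname(r[2]), 8 / 9)    # pseudocount added to all RNA>0 cells
  expect_equal(unname(r[3]), 0)        # present but silent
  expect_true(is.na(r[4]))             # absent, not zero
  expect_equal(sum(isAbsent(rm)), 1)

  # the pseudocount contract is enforced
  raw <- pairedSet(rbind(c(0L, 1L)), rbind(c(2L, 1L)))
  expect_error(rnaDnaRatio(raw), "pseudocountAdjust")
})

test_that("activity calls use >= by default and > in strict mode", {
  ds <- adjustedSet(rbind(c(8L, 9L, 19L)), rbind(c(8L, 9L, 9L)))
  rm <- rnaDnaRatio(ds)   # adjusted DNA: 9, 10, 20 -> ratios 8/9, 0.9, 0.45
  ds2 <- adjustedSet(rbind(c(4L,  1L)), rbind(c(4L, 2L)))
  rm2 <- rnaDnaRatio(ds2) # adjusted DNA: 5, 2 -> ratios 0.8, 1.0

  at <- classifyActivity(rm2, threshold = 1)
  expect_equal(unname(activityStates(at)[1, ]), c("inactive", "active"))
  atStrict <- classifyActivity(rm2, threshold = 1, strict = TRUE)
  expect_equal(unname(activityStates(atStrict)[1, ]), c("inactive", "inactive"))

  at05 <- classifyActivity(rm, threshold = 0.5)
  expect_equal(unname(activityStates(at05)[1, 3]), "inactive")  # 0.45 < 0.5

  # >= and > differ only at cells exactly on the threshold
  for (seed in 1:20) {
    set.seed(seed)
    ds <- adjustedSet(matrix(rpois(24, 4), 2, 12), matrix(rpois(24, 4), 2, 12),
                      subjects = c("B1", "B2"))
    rm <- rnaDnaRatio(ds)
    for (th in c(0.5, 1, 2)) {
      lax <- activityStates(classifyActivity(rm, th))
      strict <- activityStates(classifyActivity(rm, th, strict = TRUE))
      differ <- which(lax != strict)
      expect_true(all(abs(ratios(rm)[differ] - th) < 1e-12))
    }
  }
})

test_that("active sets nest as the threshold grows", {
  for (seed in 1:30) {
    set.seed(seed)
    ds <- adjustedSet(matrix(rpois(30, 3), 3, 10), matrix(rpois(30, 3), 3, 10))
    rm <- rnaDnaRatio(ds)
    act <- lapply(c(0.5, 1, 2), function(th)
      which(activityStates(classifyActivity(rm, th)) == "active"))
    expect_true(all(act[[3]] %in% act[[2]]))
    expect_true(all(act[[2]] %in% act[[1]]))
  }
})

activityFromStates <- function(states, subjects, threshold = 1) {
  pairs <- data.frame(subject_id = subjects, timepoint = "pre",
                      treatment = "control",
                      dna_sample = paste0(subjects, "_D"),
                      rna_sample = paste0(subjects, "_R"),
                      pair_id = subjects, stringsAsFactors = FALSE)
  new("ActivityTable", states = states, threshold = threshold,
      strict = FALSE, pairs = pairs)
}

test_that("shift coding follows the policy table for absent states", {
  statesOf <- function(v) matrix(v, 1, length(v),
                                 dimnames = list("B1", paste0("a", seq_along(v))))
  pre <- activityFromStates(statesOf(c("active", "active", "inactive",
                                       "inactive", "absent", "absent")), "B1")
  post <- activityFromStates(statesOf(c("active", "inactive", "active",
                                        "inactive", "active", "absent")), "B1")
  st <- shiftCode(pre, post)
  expect_equal(unname(shiftCodes(st)[1, ]),
               c(0L, -1L, 1L, 0L, NA, NA))          # default: absent undefined
  stIn <- shiftCode(pre, post, absentPolicy = "inactive")
  expect_equal(unname(shiftCodes(stIn)[1, ]),
               c(0L, -1L, 1L, 0L, 1L, 0L))          # absent-as-inactive

  # mismatched thresholds refuse to combine
  post2 <- activityFromStates(statesOf(rep("active", 6)), "B1", threshold = 2)
  expect_error(shiftCode(pre, post2), "threshold")
})

test_that("shift distances are Euclidean over subjects' code vectors", {
  codes <- rbind(B1 = c(1L, 0L, -1L), B2 = c(0L, 0L, -1L), B3 = c(1L, 1L, NA))
  colnames(codes) <- paste0("a", 1:3)
  st <- new("ShiftTable", codes = codes, threshold = 1)
  d <- shiftDistance(st)                             # NA imputed as 0
  m <- as.matrix(d)
  expect_equal(m["B1", "B2"], 1)                     # sqrt(1^2)
  expect_equal(m["B2", "B3"], sqrt(1 + 1 + 1))
  expect_equal(attr(d, "n_imputed"), 1)

  codes2 <- rbind(B1 = c(1L, 1L), B2 = c(-1L, -1L), B3 = c(0L, 0L))
  st2 <- new("ShiftTable", codes = codes2, threshold = 1)
  expect_equal(as.matrix(shiftDistance(st2))["B1", "B2"], sqrt(8))

  dDrop <- shiftDistance(st, undefined = "drop")     # a3 has no NA, a1/a2 kept
  expect_equal(attr(dDrop, "n_dropped"), 1)

  one <- new("ShiftTable", codes = codes[1:2, , drop = FALSE], threshold = 1)
  expect_error(shiftDistance(one), "3 subjects")
})

test_that("susceptible taxa shift to inactivity more often under a bacteriostatic hit", {
  cfg <- scenarioConfig(n_subjects = 6, n_control = 0, n_asvs = 150,
                        frac_dead = 0.2, frac_transient = 0,
                        frac_dormant = 0, a_hi = 1, a_lo = 0.05,
                        rrna_factor = 2, frac_susceptible = 0.4,
                        treatment_f = 0.05, drift_sd = 0,
                        dna_depth_range = c(20000, 20000),
                        rna_depth_range = c(20000, 20000), seed = 42)
  study <- generateStudy(cfg)
  res <- suppressWarnings(runAnalysis(pipelineConfig(dnaCounts(study$dataset),
                                    rnaCounts(study$dataset), study$metadata,
                                    seed = 7, permutations = 99,
                                    thresholds = 0.5),
                     withr::local_tempdir()))
  st <- shiftCodes(res$shifts[["0.5"]]$shifts)
  truthPre <- study$truth[study$truth$timepoint == "pre" &
                            study$truth$subject_id == "S1", ]
  sus <- truthPre$asv_id[truthPre$susceptible]
  rateS <- mean(st[, colnames(st) %in% sus] == -1L, na.rm = TRUE)
  rateN <- mean(st[, !(colnames(st) %in% sus)] == -1L, na.rm = TRUE)
  expect_gt(rateS, rateN)
  expect_gt(rateS, 0.5)
})
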