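# Fixtures and independent oracles used across the suite.

ct <- function(m, samples = NULL, asvs = NULL) {
  if (is.null(rownames(m)))
    rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- asvs %||% paste0("asv", seq_len(ncol(m)))
  CountTable(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a PairedAmpliconSet directly from two samples-x-ASVs matrices whose
# rows are swab events in (subject, timepoint) order. Construct via new()
# so property loops stay cheap; inputs are valid by construction.
pairedSet <- function(dnaM, rnaM, subjects = NULL, timepoints = NULL,
                      treatments = NULL) {
  n <- nrow(dnaM)
  if (is.null(subjects)) subjects <- paste0("B", seq_len(n))
  if (is.null(timepoints)) timepoints <- rep("pre", n)
  if (is.null(treatments)) treatments <- rep("control", n)
  pid <- paste(subjects, timepoints, sep = "_")
  dimnames(dnaM) <- list(paste0(pid, "_DNA"),
                         colnames(dnaM) %||% paste0("asv", seq_len(ncol(dnaM))))
  dimnames(rnaM) <- list(paste0(pid, "_RNA"), colnames(dnaM))
  storage.mode(dnaM) <- "integer"
  storage.mode(rnaM) <- "integer"
  pairs <- data.frame(subject_id = subjects, timepoint = timepoints,
                      treatment = treatments,
                      dna_sample = rownames(dnaM), rna_sample = rownames(rnaM),
                      pair_id = pid, stringsAsFactors = FALSE)
  meta <- rbind(
    data.frame(sample_id = rownames(dnaM), subject_id = subjects,
               timepoint = timepoints, treatment = treatments,
               nucleic_acid = "DNA", stringsAsFactors = FALSE),
    data.frame(sample_id = rownames(rnaM), subject_id = subjects,
               timepoint = timepoints, treatment = treatments,
               nucleic_acid = "RNA", stringsAsFactors = FALSE))
  new("PairedAmpliconSet", dna = new("CountTable", counts = dnaM),
      rna = new("CountTable", counts = rnaM), pairs = pairs, metadata = meta)
}

# Random paired set: Poisson counts with some sparsity, pre/post per subject.
randomPairedSet <- function(seed, nSubjects = 3, nASVs = 15, lambda = 4) {
  set.seed(seed)
  n <- nSubjects * 2L
  mk <- function() {
    m <- matrix(rpois(n * nASVs, lambda) *
                  rbinom(n * nASVs, 1L, 0.6), n, nASVs)
    m[rowSums(m) == 0, 1L] <- 1L   # keep samples non-empty
    m
  }
  pairedSet(mk(), mk(),
            subjects = rep(paste0("B", seq_len(nSubjects)), each = 2L),
            timepoints = rep(c("pre", "post"), nSubjects),
            treatments = rep(c("control", "antibiotic"),
                             length.out = nSubjects)[rep(seq_len(nSubjects), each = 2L)])
}

# --- independent oracles ----------------------------------------------------

# all permutations of seq_len(n), rows of a matrix (n <= 7)
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Brute-force BH step-up: adj_(k) = min_{i >= k} p_(i) * m / i, capped at 1.
bhBruteForce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (k in seq_len(m))
    adj[k] <- min(1, min(ps[k:m] * m / (k:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# pseudo-F from a square distance matrix and group labels
pseudoF <- function(m, groups) {
  groups <- as.factor(groups)
  n <- nrow(m)
  k <- nlevels(groups)
  d2 <- m^2
  ssT <- sum(d2[upper.tri(d2)]) / n
  ssW <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ssW <- ssW + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ssA <- ssT - ssW
  (ssA / (k - 1)) / (ssW / (n - k))
}

# exact PERMANOVA p by full enumeration of label permutations
permanovaExactP <- function(m, groups) {
  fObs <- pseudoF(m, groups)
  P <- allPerms(nrow(m))
  fAll <- apply(P, 1L, function(idx) pseudoF(m, groups[idx]))
  mean(fAll >= fObs - 1e-10)
}

# exact one-sided Mantel p by full enumeration
mantelExact <- function(m1, m2) {
  v <- function(m) m[upper.tri(m)]
  rObs <- cor(v(m1), v(m2))
  P <- allPerms(nrow(m1))
  rAll <- apply(P, 1L, function(idx) cor(v(m1[idx, idx]), v(m2)))
  list(r = rObs, p = mean(rAll >= rObs - 1e-10))
}
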