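#' Per-pair, per-ASV RNA:DNA ratios
#'
#' Elementwise RNA count over (pseudocount-adjusted) DNA count for each
#' sample pair. Run after [rarefyDataset()] and [pseudocountAdjust()]: the
#' adjustment guarantees a positive DNA count wherever RNA is positive, so
#' no division by zero can occur. Cells with both counts zero say nothing
#' about the taxon in that pair and are flagged absent (`NA`), not zero;
#' cells with RNA = 0 but DNA > 0 have ratio 0 (present but silent).
#'
#' @param ds a rarefied, pseudocount-adjusted [PairedAmpliconSet-class].
#' @return a [RatioMatrix-class].
#' @export
rnaDnaRatio <- function(ds) {
  stopifnot(is(ds, "PairedAmpliconSet"))
  p <- samplePairs(ds)
  dnaM <- counts(dnaCounts(ds))[p$dna_sample, , drop = FALSE]
  rnaM <- counts(rnaCounts(ds))[p$rna_sample, , drop = FALSE]
  if (any(rnaM > 0L & dnaM == 0L))
    stop("internal error: RNA > 0 with DNA = 0 — run pseudocountAdjust() first")
  r <- rnaM / ifelse(dnaM == 0L, NA_real_, dnaM)
  r[rnaM == 0L & dnaM > 0L] <- 0
  # rnaM==0 & dnaM==0 stays NA: absent
  rownames(r) <- p$pair_id
  new("RatioMatrix", ratios = r, pairs = p)
}

#' Classify ASVs as active or inactive at an RNA:DNA threshold
#'
#' An ASV in a pair is called active when its RNA:DNA ratio reaches the
#' threshold; otherwise inactive. Absent cells propagate. The commonly
#' used cut-offs are 0.5 (assumes roughly half the population active, or
#' extra 16S gene copies / relic DNA), 1, and 2 (more rRNA than gene
#' copies per cell). The boundary comparison is `>=` by default; set
#' `strict = TRUE` for `>`, which differs only at cells exactly on the
#' threshold.
#'
#' @param rm a [RatioMatrix-class].
#' @param threshold positive cut-off (0.5, 1 and 2 are conventional).
#' @param strict use `>` instead of `>=` at the boundary.
#' @return an [ActivityTable-class].
#' @export
classifyActivity <- function(rm, threshold, strict = FALSE) {
  stopifnot(is(rm, "RatioMatrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a single positive number")
  r <- ratios(rm)
  st <- matrix("absent", nrow(r), ncol(r), dimnames = dimnames(r))
  hit <- if (strict) r > threshold else r >= threshold
  st[!is.na(r) & hit] <- "active"
  st[!is.na(r) & !hit] <- "inactive"
  new("ActivityTable", states = st, threshold = threshold,
      strict = strict, pairs = samplePairs(rm))
}

#' Code pre-to-post shifts in activity state
#'
#' For each subject and ASV: a shift to inactivity is coded -1, a shift to
#' activity +1, no shift 0. Under the default policy any transition
#' involving an absent state is undefined (`NA`), because taxa absent at
#' one timepoint can skew shift analyses if silently recoded;
#' `absentPolicy = "inactive"` instead treats absent as inactive
#' (replicating less careful pipelines).
#'
#' @param pre,post [ActivityTable-class] objects for the two timepoints,
#'   called at the same threshold and boundary mode.
#' @param absentPolicy `"undefined"` (default) or `"inactive"`.
#' @return a [ShiftTable-class] (subjects x ASVs).
#' @export
shiftCode <- function(pre, post, absentPolicy = c("undefined", "inactive")) {
  absentPolicy <- match.arg(absentPolicy)
  stopifnot(is(pre, "ActivityTable"), is(post, "ActivityTable"))
  if (!isTRUE(all.equal(pre@threshold, post@threshold)) ||
      !identical(pre@strict, post@strict))
    stop("pre and post activity tables use different thresholds or boundary modes")
  if (!identical(colnames(pre@states), colnames(post@states)))
    stop("pre and post activity tables cover different ASVs")
  preSub <- samplePairs(pre)$subject_id
  postSub <- samplePairs(post)$subject_id
  subjects <- intersect(preSub, postSub)
  if (!length(subjects))
    stop("no subjects shared between the two timepoints")

  codeOne <- function(a, b) {
    if (absentPolicy == "inactive") {
      a[a == "absent"] <- "inactive"
      b[b == "absent"] <- "inactive"
    }
    out <- rep(NA_integer_, length(a))
    defined <- a != "absent" & b != "absent"
    out[defined & a == b] <- 0L
    out[defined & a == "active" & b == "inactive"] <- -1L
    out[defined & a == "inactive" & b == "active"] <- 1L
    out
  }
  codes <- t(vapply(subjects, function(s) {
    codeOne(pre@states[match(s, preSub), ],
            post@states[match(s, postSub), ])
  }, integer(ncol(pre@states))))
  rownames(codes) <- subjects
  colnames(codes) <- colnames(pre@states)
  new("ShiftTable", codes = codes, threshold = pre@threshold)
}

#' Euclidean distance between subjects' activity-shift vectors
#'
#' Distance matrix over subjects computed from their shift-code vectors
#' across ASVs. Undefined codes are imputed as 0 (no evidence of a shift)
#' by default and the number imputed is recorded; `undefined = "drop"`
#' instead removes any ASV with an undefined code in any subject.
#'
#' @param st a [ShiftTable-class] over at least 3 subjects.
#' @param undefined `"zero"` (default) or `"drop"`.
#' @return a `dist` over subjects, with attribute `"n_imputed"` (or
#'   `"n_dropped"`).
#' @export
shiftDistance <- function(st, undefined = c("zero", "drop")) {
  undefined <- match.arg(undefined)
  stopifnot(is(st, "ShiftTable"))
  v <- shiftCodes(st)
  if (nrow(v) < 3L)
    stop("need at least 3 subjects for a usable shift distance matrix")
  if (undefined == "zero") {
    nFix <- sum(is.na(v))
    v[is.na(v)] <- 0L
    d <- stats::dist(v, method = "euclidean")
    attr(d, "n_imputed") <- nFix
  } else {
    keep <- colSums(is.na(v)) == 0L
    d <- stats::dist(v[, keep, drop = FALSE], method = "euclidean")
    attr(d, "n_dropped") <- sum(!keep)
  }
  d
}

#' Export a RatioMatrix, ActivityTable or ShiftTable as tidy TSV
#'
#' Long format: one row per defined (row, ASV) cell.
#'
#' @param x a [RatioMatrix-class], [ActivityTable-class] or
#'   [ShiftTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeActivityTSV <- function(x, path) {
  if (is(x, "RatioMatrix")) {
    m <- ratios(x)
    df <- data.frame(pair_id = rep(rownames(m), ncol(m)),
                     asv_id = rep(colnames(m), each = nrow(m)),
                     ratio = as.vector(m))
    df <- df[!is.na(df$ratio), ]
  } else if (is(x, "ActivityTable")) {
    m <- activityStates(x)
    df <- data.frame(pair_id = rep(rownames(m), ncol(m)),
                     asv_id = rep(colnames(m), each = nrow(m)),
                     threshold = activityThreshold(x),
                     status = as.vector(m))
  } else if (is(x, "ShiftTable")) {
    m <- shiftCodes(x)
    df <- data.frame(subject_id = rep(rownames(m), ncol(m)),
                     asv_id = rep(colnames(m), each = nrow(m)),
                     threshold = activityThreshold(x),
                     code = as.vector(m))
  } else stop("unsupported object")
  df <- df[order(df[[1L]], df$asv_id), ]
  writeTSV(df, path)
}
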