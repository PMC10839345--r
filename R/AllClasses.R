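#' CountTable: a samples-by-ASVs amplicon count matrix
#'
#' Thin S4 container for a denoised feature table. Rows are samples, columns
#' are amplicon sequence variants (ASVs), entries are non-negative integer
#' read counts. Row/column names are the sample and ASV identifiers and must
#' be unique. Samples-as-rows matches the orientation expected by the
#' \pkg{vegan} functions this package builds on.
#'
#' @slot counts integer matrix, samples x ASVs, with unique dimnames.
#'
#' @seealso [readCountTable()], [buildPairedDataset()]
#' @export
setClass("CountTable", slots = c(counts = "matrix"))

setValidity("CountTable", function(object) {
  m <- object@counts
  msg <- character()
  if (!is.numeric(m))
    msg <- c(msg, "counts must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have sample (row) and ASV (column) names")
  else {
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, "duplicated sample ids")
    if (anyDuplicated(colnames(m)))
      msg <- c(msg, "duplicated ASV ids")
  }
  if (is.numeric(m)) {
    if (anyNA(m))
      msg <- c(msg, "counts contain NA")
    else {
      if (any(m < 0))
        msg <- c(msg, "counts contain negative entries")
      if (is.double(m) && any(m != round(m)))
        msg <- c(msg, "counts contain non-integral entries")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CountTable
#'
#' @param counts numeric matrix of non-negative, integral read counts with
#'   samples as rows and ASVs as columns (set `orientation = "asv_rows"` if
#'   ASVs are rows). Dimnames are required and must be unique.
#' @param orientation `"sample_rows"` (default) or `"asv_rows"`; the latter
#'   transposes the input, matching the common denoiser export with features
#'   as rows.
#' @return A validated [CountTable-class] object with integer storage.
#' @examples
#' m <- matrix(c(1L, 2L, 3L, 4L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("asv1", "asv2")))
#' CountTable(m)
#' @export
CountTable <- function(counts, orientation = c("sample_rows", "asv_rows")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(counts))
    stop("'counts' must be a matrix")
  if (orientation == "asv_rows")
    counts <- t(counts)
  if (is.double(counts)) {
    if (anyNA(counts) || any(counts != round(counts)))
      stop("counts contain NA or non-integral entries")
    storage.mode(counts) <- "integer"
  }
  new("CountTable", counts = counts)
}

#' @describeIn CountTable-class the count matrix (samples x ASVs)
#' @param object,x a `CountTable`
#' @export
setMethod("counts", "CountTable", function(object) object@counts)

#' @describeIn CountTable-class sample identifiers (row names)
#' @export
setMethod("sampleIDs", "CountTable", function(object) rownames(object@counts))

#' @describeIn CountTable-class ASV identifiers (column names)
#' @export
setMethod("asvIDs", "CountTable", function(object) colnames(object@counts))

#' @describeIn CountTable-class number of samples
#' @export
setMethod("nSamples", "CountTable", function(object) nrow(object@counts))

#' @describeIn CountTable-class number of ASVs
#' @export
setMethod("nASVs", "CountTable", function(object) ncol(object@counts))

#' @describeIn CountTable-class subset by sample and/or ASV
#' @param i,j,...,drop sample / ASV index as in matrix subsetting (`drop`
#'   is ignored; the result is always a `CountTable`)
#' @export
setMethod("[", "CountTable", function(x, i, j, ..., drop = FALSE) {
  m <- x@counts[i, j, drop = FALSE]
  new("CountTable", counts = m)
})

setMethod("show", "CountTable", function(object) {
  cat("CountTable:", nrow(object@counts), "samples x",
      ncol(object@counts), "ASVs\n")
  tot <- rowSums(object@counts)
  cat("  reads/sample: min", min(tot), "median", stats::median(tot),
      "max", max(tot), "\n")
})

# ---------------------------------------------------------------------------

#' PairedAmpliconSet: aligned DNA and RNA count tables
#'
#' The central container of the package: one DNA-derived and one RNA(cDNA)-
#' derived [CountTable-class] over an identical, identically ordered ASV
#' list, together with the pairing of DNA and RNA samples taken from the
#' same swab event (one subject at one timepoint) and the per-sample
#' metadata. Built with [buildPairedDataset()].
#'
#' @slot dna,rna `CountTable` objects sharing the same ASV ids in the
#'   same order.
#' @slot pairs data.frame with one row per (subject, timepoint) swab event:
#'   columns `subject_id`, `timepoint` ("pre"/"post"), `treatment`
#'   ("control"/"antibiotic"), `dna_sample`, `rna_sample`, `pair_id`.
#' @slot metadata data.frame of per-sample metadata (columns `sample_id`,
#'   `subject_id`, `timepoint`, `treatment`, `nucleic_acid`).
#'
#' @export
setClass("PairedAmpliconSet",
         slots = c(dna = "CountTable", rna = "CountTable",
                   pairs = "data.frame", metadata = "data.frame"))

setValidity("PairedAmpliconSet", function(object) {
  msg <- character()
  if (!identical(asvIDs(object@dna), asvIDs(object@rna)))
    msg <- c(msg, "DNA and RNA tables must share identical, identically ordered ASV ids")
  p <- object@pairs
  need <- c("subject_id", "timepoint", "treatment", "dna_sample",
            "rna_sample", "pair_id")
  if (!all(need %in% names(p)))
    msg <- c(msg, paste("pairs must have columns:", paste(need, collapse = ", ")))
  else {
    if (!all(p$dna_sample %in% sampleIDs(object@dna)))
      msg <- c(msg, "pairs reference DNA samples missing from the DNA table")
    if (!all(p$rna_sample %in% sampleIDs(object@rna)))
      msg <- c(msg, "pairs reference RNA samples missing from the RNA table")
    if (anyDuplicated(p$pair_id))
      msg <- c(msg, "duplicated pair ids")
    if (anyDuplicated(paste(p$subject_id, p$timepoint)))
      msg <- c(msg, "more than one pair for a (subject, timepoint)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PairedAmpliconSet-class the DNA count table
#' @param object a `PairedAmpliconSet`
#' @export
setMethod("dnaCounts", "PairedAmpliconSet", function(object) object@dna)

#' @describeIn PairedAmpliconSet-class the RNA count table
#' @export
setMethod("rnaCounts", "PairedAmpliconSet", function(object) object@rna)

#' @describeIn PairedAmpliconSet-class the pairing table (one row per swab event)
#' @export
setMethod("samplePairs", "PairedAmpliconSet", function(object) object@pairs)

#' @describeIn PairedAmpliconSet-class per-sample metadata
#' @export
setMethod("sampleData", "PairedAmpliconSet", function(object) object@metadata)

#' @describeIn PairedAmpliconSet-class shared ASV identifiers
#' @export
setMethod("asvIDs", "PairedAmpliconSet", function(object) asvIDs(object@dna))

#' @describeIn PairedAmpliconSet-class number of shared ASVs
#' @export
setMethod("nASVs", "PairedAmpliconSet", function(object) nASVs(object@dna))

setMethod("show", "PairedAmpliconSet", function(object) {
  cat("PairedAmpliconSet:", nrow(object@pairs), "sample pairs,",
      nASVs(object), "ASVs\n")
  tp <- table(object@pairs$timepoint)
  cat("  timepoints:", paste(names(tp), tp, sep = "=", collapse = ", "), "\n")
  cat("  subjects:", length(unique(object@pairs$subject_id)), "\n")
})

# ---------------------------------------------------------------------------

#' FilterReport: provenance record for one filtering step
#'
#' @slot filter name of the filtering step.
#' @slot params parameters the step ran with.
#' @slot asvsRemoved ids of ASVs dropped from the dataset.
#' @slot readsRemoved total reads removed, by table (`dna`, `rna`).
#'
#' @export
setClass("FilterReport",
         slots = c(filter = "character", params = "list",
                   asvsRemoved = "character", readsRemoved = "numeric"))

setValidity("FilterReport", function(object) {
  if (any(object@readsRemoved < 0)) "readsRemoved must be non-negative" else TRUE
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport <", object@filter, ">: ",
      length(object@asvsRemoved), " ASVs removed, ",
      sum(object@readsRemoved), " reads removed\n", sep = "")
})

# ---------------------------------------------------------------------------

#' RatioMatrix: per-pair, per-ASV RNA:DNA ratios
#'
#' Rows are sample pairs (swab events), columns ASVs. Cells where both the
#' RNA and the (adjusted) DNA count are zero carry no information about the
#' taxon in that pair and are flagged absent (stored `NA`), never zero.
#'
#' @slot ratios numeric matrix, pairs x ASVs; `NA` marks absent cells.
#' @slot pairs the pairing table the rows refer to.
#'
#' @export
setClass("RatioMatrix", slots = c(ratios = "matrix", pairs = "data.frame"))

setValidity("RatioMatrix", function(object) {
  r <- object@ratios
  msg <- character()
  if (any(r < 0, na.rm = TRUE)) msg <- c(msg, "negative ratios")
  if (!identical(nrow(r), nrow(object@pairs)))
    msg <- c(msg, "ratio rows must match the pairing table")
  if (length(msg)) msg else TRUE
})

#' @describeIn RatioMatrix-class the ratio matrix (NA = absent)
#' @param object a `RatioMatrix`
#' @export
setMethod("ratios", "RatioMatrix", function(object) object@ratios)

#' @describeIn RatioMatrix-class logical matrix of absent cells
#' @export
setMethod("isAbsent", "RatioMatrix", function(object) is.na(object@ratios))

#' @describeIn RatioMatrix-class the pairing table
#' @export
setMethod("samplePairs", "RatioMatrix", function(object) object@pairs)

setMethod("show", "RatioMatrix", function(object) {
  cat("RatioMatrix:", nrow(object@ratios), "pairs x", ncol(object@ratios),
      "ASVs;", sum(is.na(object@ratios)), "absent cells\n")
})

# ---------------------------------------------------------------------------

#' ActivityTable: active/inactive/absent calls at one RNA:DNA threshold
#'
#' @slot states character matrix (pairs x ASVs) with values `"active"`,
#'   `"inactive"`, `"absent"`.
#' @slot threshold the RNA:DNA cut-off used.
#' @slot strict `FALSE` (default) calls active when ratio >= threshold;
#'   `TRUE` requires ratio > threshold.
#' @slot pairs the pairing table the rows refer to.
#'
#' @export
setClass("ActivityTable",
         slots = c(states = "matrix", threshold = "numeric",
                   strict = "logical", pairs = "data.frame"))

setValidity("ActivityTable", function(object) {
  msg <- character()
  ok <- object@states %in% c("active", "inactive", "absent")
  if (!all(ok)) msg <- c(msg, "states must be active/inactive/absent")
  if (length(object@threshold) != 1L || object@threshold <= 0)
    msg <- c(msg, "threshold must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @describeIn ActivityTable-class the state matrix
#' @param object an `ActivityTable`
#' @export
setMethod("activityStates", "ActivityTable", function(object) object@states)

#' @describeIn ActivityTable-class the RNA:DNA cut-off used
#' @export
setMethod("activityThreshold", "ActivityTable", function(object) object@threshold)

#' @describeIn ActivityTable-class the pairing table
#' @export
setMethod("samplePairs", "ActivityTable", function(object) object@pairs)

setMethod("show", "ActivityTable", function(object) {
  tab <- table(factor(object@states, c("active", "inactive", "absent")))
  cat("ActivityTable @ threshold ", object@threshold,
      if (object@strict) " (strict >)" else " (>=)", ": ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
})

# ---------------------------------------------------------------------------

#' ShiftTable: per-subject, per-ASV activity shift codes
#'
#' Codes the pre-to-post change in activity state: -1 a shift to
#' inactivity, +1 a shift to activity, 0 no shift, `NA` undefined (the ASV
#' was absent at one or both timepoints under the default policy).
#'
#' @slot codes integer matrix, subjects x ASVs, values in \{-1, 0, 1, NA\}.
#' @slot threshold the RNA:DNA cut-off the states were called at.
#'
#' @export
setClass("ShiftTable", slots = c(codes = "matrix", threshold = "numeric"))

setValidity("ShiftTable", function(object) {
  v <- object@codes
  if (!all(v %in% c(-1L, 0L, 1L, NA_integer_)))
    "codes must be -1, 0, 1 or NA" else TRUE
})

#' @describeIn ShiftTable-class the code matrix (subjects x ASVs)
#' @param object a `ShiftTable`
#' @export
setMethod("shiftCodes", "ShiftTable", function(object) object@codes)

#' @describeIn ShiftTable-class the RNA:DNA cut-off the calls used
#' @export
setMethod("activityThreshold", "ShiftTable", function(object) object@threshold)

setMethod("show", "ShiftTable", function(object) {
  v <- object@codes
  cat("ShiftTable @ threshold ", object@threshold, ": ",
      nrow(v), " subjects x ", ncol(v), " ASVs; ",
      sum(v == -1L, na.rm = TRUE), " to-inactive, ",
      sum(v == 1L, na.rm = TRUE), " to-active, ",
      sum(is.na(v)), " undefined\n", sep = "")
})
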