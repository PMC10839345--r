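#' Remove phantom reads
#'
#' Phantom reads are RNA-sample reads for an ASV that is absent from the
#' paired DNA sample: because the RNA community is defined as a subset of
#' the DNA-detected community, such reads are treated as artifact and
#' zeroed. The default scope is per pair — an ASV can be phantom in one
#' swab event and real in another. `scope = "global"` instead zeroes RNA
#' for ASVs with no DNA reads in any sample (a sensitivity-analysis mode).
#' ASVs left with zero counts in both tables are dropped from both.
#'
#' After this step RNA support is a subset of DNA support within every
#' pair, which also guarantees per-pair proportion-living values in (0, 1].
#'
#' @param ds a [PairedAmpliconSet-class].
#' @param scope `"pair"` (default) or `"global"`.
#' @return list with elements `dataset` (filtered set) and `report`
#'   (a [FilterReport-class]).
#' @export
removePhantomReads <- function(ds, scope = c("pair", "global")) {
  scope <- match.arg(scope)
  stopifnot(is(ds, "PairedAmpliconSet"))
  dnaM <- counts(dnaCounts(ds))
  rnaM <- counts(rnaCounts(ds))
  p <- samplePairs(ds)

  rnaNew <- rnaM
  if (scope == "pair") {
    for (k in seq_len(nrow(p))) {
      d <- dnaM[p$dna_sample[k], ]
      r <- rnaNew[p$rna_sample[k], ]
      r[d == 0L] <- 0L
      rnaNew[p$rna_sample[k], ] <- r
    }
  } else {
    dead <- colSums(dnaM) == 0L
    rnaNew[, dead] <- 0L
  }
  removedReads <- sum(rnaM) - sum(rnaNew)

  keep <- colSums(dnaM) + colSums(rnaNew) > 0L
  report <- new("FilterReport", filter = "phantom_reads",
                params = list(scope = scope),
                asvsRemoved = colnames(rnaM)[!keep],
                readsRemoved = c(dna = 0, rna = removedReads))
  out <- new("PairedAmpliconSet",
             dna = new("CountTable", counts = dnaM[, keep, drop = FALSE]),
             rna = new("CountTable", counts = rnaNew[, keep, drop = FALSE]),
             pairs = p, metadata = sampleData(ds))
  list(dataset = out, report = report)
}

#' Keep abundant ASVs
#'
#' Retains an ASV if, in at least one sample (DNA or RNA), its count is at
#' least `threshold` of that sample's total reads (comparison is `>=`, so
#' an ASV at exactly the threshold is kept). Dropped ASVs are removed from
#' both tables. A sample with zero total reads contributes no qualifying
#' ASVs and triggers a warning.
#'
#' The screen is idempotent: rerunning it on its own output changes
#' nothing, because removing columns only increases the surviving ASVs'
#' per-sample proportions.
#'
#' @param ds a [PairedAmpliconSet-class].
#' @param threshold fraction in (0, 1); default 0.01 (1\% of a sample's
#'   reads).
#' @return list with elements `dataset` and `report`.
#' @export
abundanceFilter <- function(ds, threshold = 0.01) {
  stopifnot(is(ds, "PairedAmpliconSet"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must be a single fraction in (0, 1)")
  m <- rbind(counts(dnaCounts(ds)), counts(rnaCounts(ds)))
  tot <- rowSums(m)
  if (any(tot == 0))
    warning("samples with zero total reads: ",
            paste(rownames(m)[tot == 0], collapse = ", "))
  ok <- tot > 0
  prop <- m[ok, , drop = FALSE] / tot[ok]
  keep <- apply(prop, 2L, max) >= threshold
  if (!any(keep))
    stop("abundance filter removed every ASV")

  dnaM <- counts(dnaCounts(ds))
  rnaM <- counts(rnaCounts(ds))
  readsRemoved <- c(dna = sum(dnaM[, !keep]), rna = sum(rnaM[, !keep]))
  report <- new("FilterReport", filter = "abundance",
                params = list(threshold = threshold),
                asvsRemoved = colnames(m)[!keep],
                readsRemoved = readsRemoved)
  out <- new("PairedAmpliconSet",
             dna = new("CountTable", counts = dnaM[, keep, drop = FALSE]),
             rna = new("CountTable", counts = rnaM[, keep, drop = FALSE]),
             pairs = samplePairs(ds), metadata = sampleData(ds))
  list(dataset = out, report = report)
}

#' Rarefy a count table to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' (via \code{\link[vegan]{rrarefy}} under a caller-supplied seed).
#' Every output row sums exactly to `depth` and no cell exceeds its input
#' count; rerunning with the same seed is bit-identical.
#'
#' @param ct a [CountTable-class].
#' @param depth target reads per sample; every retained sample must have
#'   at least this many reads.
#' @param seed integer seed (required: the subsample is random).
#' @param dropShallow if `TRUE`, samples below `depth` are dropped with a
#'   warning instead of raising an error.
#' @return rarefied [CountTable-class].
#' @export
rarefyCounts <- function(ct, depth, seed, dropShallow = FALSE) {
  stopifnot(is(ct, "CountTable"))
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    stop("'depth' must be a positive integer")
  depth <- as.integer(depth)
  m <- counts(ct)
  tot <- rowSums(m)
  shallow <- tot < depth
  if (any(shallow)) {
    if (!dropShallow)
      stop("samples below rarefaction depth ", depth, ": ",
           paste(rownames(m)[shallow], collapse = ", "))
    warning("dropping samples below depth ", depth, ": ",
            paste(rownames(m)[shallow], collapse = ", "))
    m <- m[!shallow, , drop = FALSE]
  }
  # vegan warns on tables whose smallest count exceeds 1 (a heuristic for
  # already-transformed data); our inputs are validated integer counts.
  r <- withSeed(seed, withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  storage.mode(r) <- "integer"
  new("CountTable", counts = r)
}

#' Rarefy both tables of a paired dataset
#'
#' @param ds a [PairedAmpliconSet-class].
#' @param depth target depth, or `"auto"` for the minimum total across all
#'   DNA and RNA samples (the lowest read depth in the dataset).
#' @param seed integer seed.
#' @return list: `dataset` (rarefied set) and `depth` (the depth used).
#' @export
rarefyDataset <- function(ds, depth = "auto", seed) {
  stopifnot(is(ds, "PairedAmpliconSet"))
  if (identical(depth, "auto"))
    depth <- min(rowSums(counts(dnaCounts(ds))),
                 rowSums(counts(rnaCounts(ds))))
  seeds <- withSeed(seed, drawSeeds(2L))
  out <- new("PairedAmpliconSet",
             dna = rarefyCounts(dnaCounts(ds), depth, seeds[1L]),
             rna = rarefyCounts(rnaCounts(ds), depth, seeds[2L]),
             pairs = samplePairs(ds), metadata = sampleData(ds))
  list(dataset = out, depth = as.integer(depth))
}

#' Pseudocount adjustment for RNA:DNA ratios
#'
#' Rarefaction can zero a DNA count whose paired RNA count stayed positive,
#' recreating apparent phantom reads and making the RNA:DNA ratio
#' undefined. The adjustment adds 1 to the DNA count of any (pair, ASV)
#' cell whose paired RNA count is positive; RNA counts are untouched. The
#' default mode applies the increment to every RNA-positive cell
#' (`mode = "all"`); `mode = "zeros"` increments only cells where the DNA
#' count is zero. Either way, no (RNA > 0, DNA = 0) cell remains.
#'
#' @param ds a rarefied [PairedAmpliconSet-class].
#' @param mode `"all"` (default) or `"zeros"`.
#' @return adjusted [PairedAmpliconSet-class].
#' @export
pseudocountAdjust <- function(ds, mode = c("all", "zeros")) {
  mode <- match.arg(mode)
  stopifnot(is(ds, "PairedAmpliconSet"))
  dnaM <- counts(dnaCounts(ds))
  rnaM <- counts(rnaCounts(ds))
  p <- samplePairs(ds)
  for (k in seq_len(nrow(p))) {
    d <- dnaM[p$dna_sample[k], ]
    r <- rnaM[p$rna_sample[k], ]
    bump <- if (mode == "all") r > 0L else r > 0L & d == 0L
    dnaM[p$dna_sample[k], ] <- d + as.integer(bump)
  }
  new("PairedAmpliconSet",
      dna = new("CountTable", counts = dnaM),
      rna = new("CountTable", counts = rnaM),
      pairs = p, metadata = sampleData(ds))
}

#' Serialize filter reports to a JSON provenance file
#'
#' @param reports list of [FilterReport-class] objects.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
writeFilterReports <- function(reports, path) {
  payload <- lapply(reports, function(r) list(
    filter = r@filter, params = r@params,
    asvs_removed = r@asvsRemoved,
    reads_removed = as.list(r@readsRemoved)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
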