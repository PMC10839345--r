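#' Proportion of the DNA-detected community that is living
#'
#' For each sample pair, the number of ASVs detected in the RNA sample
#' divided by the number detected in the paired DNA sample. Run after
#' [removePhantomReads()] so that RNA support is a subset of DNA support
#' and the proportion lies in (0, 1]. Computed separately on the full and
#' on the abundant dataset by calling it on each.
#'
#' @param ds a [PairedAmpliconSet-class] with phantom reads removed.
#' @return data.frame: `pair_id`, `subject_id`, `timepoint`, `treatment`,
#'   `dna_richness`, `rna_richness`, `proportion_living` (`NA` with a
#'   warning where DNA richness is zero).
#' @export
proportionLiving <- function(ds) {
  stopifnot(is(ds, "PairedAmpliconSet"))
  dnaM <- counts(dnaCounts(ds))
  rnaM <- counts(rnaCounts(ds))
  p <- samplePairs(ds)
  dnaRich <- rowSums(dnaM[p$dna_sample, , drop = FALSE] > 0L)
  rnaRich <- rowSums(rnaM[p$rna_sample, , drop = FALSE] > 0L)
  prop <- ifelse(dnaRich > 0L, rnaRich / dnaRich, NA_real_)
  if (anyNA(prop))
    warning("pairs with zero DNA richness: ",
            paste(p$pair_id[is.na(prop)], collapse = ", "))
  data.frame(pair_id = p$pair_id, subject_id = p$subject_id,
             timepoint = p$timepoint, treatment = p$treatment,
             dna_richness = as.integer(dnaRich),
             rna_richness = as.integer(rnaRich),
             proportion_living = prop,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Alpha diversity per sample
#'
#' Richness (number of ASVs with nonzero counts), Shannon entropy and
#' Pielou's evenness. Entropy defaults to base 2 (bits); Pielou divides by
#' the log of richness in the same base, so the evenness is base-invariant.
#' Pielou is undefined (reported `NA`) when richness is 0 or 1. Intended
#' for a rarefied table so samples share a common depth.
#'
#' @param ct a [CountTable-class], typically rarefied.
#' @param base logarithm base for the entropy (default 2).
#' @return data.frame: `sample_id`, `richness`, `shannon`, `pielou`.
#' @export
alphaDiversity <- function(ct, base = 2) {
  stopifnot(is(ct, "CountTable"))
  m <- counts(ct)
  if (any(rowSums(m) == 0))
    stop("all-zero samples: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  rich <- rowSums(m > 0L)
  shan <- apply(m, 1L, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p, base = base))
  })
  piel <- ifelse(rich > 1L, shan / log(rich, base = base), NA_real_)
  data.frame(sample_id = rownames(m), richness = as.integer(rich),
             shannon = as.numeric(shan), pielou = as.numeric(piel),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Beta diversity distance matrix
#'
#' Bray-Curtis is computed on per-sample proportions (so per-sample
#' sequencing effort cancels); Jaccard is binary, on presence/absence
#' supports. Both are in [0, 1] with a zero diagonal.
#'
#' @param ct a [CountTable-class].
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return a `dist` with sample ids as labels.
#' @export
betaDiversity <- function(ct, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  stopifnot(is(ct, "CountTable"))
  m <- counts(ct)
  if (any(rowSums(m) == 0))
    stop("all-zero samples: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  if (metric == "bray_curtis") {
    prop <- m / rowSums(m)
    vegan::vegdist(prop, method = "bray")
  } else {
    vegan::vegdist(m, method = "jaccard", binary = TRUE)
  }
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Ordination for plotting only, never inference. The configuration starts
#' from the deterministic principal-coordinate (metric MDS) embedding and
#' is refined by Kruskal's stress-1 NMDS (\code{\link[vegan]{monoMDS}}),
#' so the default run is reproducible without an RNG and permuting the
#' input labels permutes the output rows. Additional random restarts are
#' available via `tries`; the lowest-stress solution wins.
#'
#' @param dm a `dist` over at least 4 objects.
#' @param k embedding dimension (default 2).
#' @param tries extra random starts (default 0 = PCoA start only).
#' @param seed seed for the random starts (required when `tries > 0`).
#' @param maxit maximum NMDS iterations per start.
#' @return list: `points` (n x k matrix, labelled), `stress` (Kruskal
#'   stress-1), `converged` (logical; best run).
#' @export
runNMDS <- function(dm, k = 2, tries = 0, seed = NULL, maxit = 200) {
  stopIfNotDist(dm)
  n <- attr(dm, "Size")
  if (n < 4L)
    stop("NMDS needs at least 4 objects")
  start <- stats::cmdscale(dm, k = k, add = TRUE)$points
  if (ncol(start) < k)
    start <- cbind(start, matrix(0, n, k - ncol(start)))
  fits <- list(vegan::monoMDS(dm, y = start, k = k, maxit = maxit))
  if (tries > 0) {
    if (is.null(seed))
      stop("random restarts need a 'seed'")
    starts <- withSeed(seed, lapply(seq_len(tries), function(i)
      matrix(stats::rnorm(n * k), n, k)))
    for (s in starts)
      fits <- c(fits, list(vegan::monoMDS(dm, y = s, k = k, maxit = maxit)))
  }
  stresses <- vapply(fits, function(f) f$stress, numeric(1L))
  best <- fits[[which.min(stresses)]]
  if (!isTRUE(best$converged) && best$stress > 1e-4)
    warning("NMDS did not converge; returning best configuration (stress ",
            signif(best$stress, 3), ")")
  pts <- best$points
  rownames(pts) <- attr(dm, "Labels")
  colnames(pts) <- paste0("NMDS", seq_len(k))
  list(points = pts, stress = best$stress,
       converged = isTRUE(best$converged))
}

#' Scatter plot of an NMDS ordination
#'
#' Convenience base-graphics plot; all inference values come from the
#' tabular outputs, never from figures.
#'
#' @param nmds result of [runNMDS()].
#' @param groups optional factor colouring the points.
#' @param main title.
#' @return invisibly, the coordinates.
#' @export
plotNMDS <- function(nmds, groups = NULL, main = "NMDS") {
  pts <- nmds$points
  col <- if (is.null(groups)) 1L else as.integer(factor(groups))
  graphics::plot(pts[, 1L], pts[, 2L], col = col, pch = 19,
                 xlab = colnames(pts)[1L], ylab = colnames(pts)[2L],
                 main = sprintf("%s (stress %.3f)", main, nmds$stress))
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 19)
  invisible(pts)
}

#' Write a labelled square distance matrix as TSV
#'
#' @param dm a `dist`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(dm, path) {
  stopIfNotDist(dm)
  writeTSV(distToFrame(dm), path)
}
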