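#' Kruskal-Wallis rank test
#'
#' Rank-based H statistic with tie correction (via
#' \code{\link[stats]{kruskal.test}}), p from the chi-squared
#' approximation with k - 1 degrees of freedom. With small group sizes
#' this is the workhorse test of the package's inferential layer. The
#' "interaction" of two factors is tested by concatenating their labels
#' into a single proxy factor (see [interactionProxy()]). When every
#' observation is identical the statistic is defined as 0 with p = 1
#' (complete ties carry no evidence).
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor), at least 2 non-empty
#'   groups.
#' @return one-row data.frame: `method`, `statistic` (H), `df`, `p_raw`.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups))
    stop("'values' and 'groups' lengths differ")
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    stop("need at least 2 non-empty groups")
  if (any(table(groups) == 0L))
    stop("empty group")
  if (length(unique(values)) == 1L)
    return(data.frame(method = "kruskal_wallis", statistic = 0,
                      df = nlevels(groups) - 1L, p_raw = 1))
  kt <- stats::kruskal.test(values, groups)
  data.frame(method = "kruskal_wallis",
             statistic = unname(kt$statistic),
             df = unname(kt$parameter),
             p_raw = kt$p.value)
}

#' Concatenated proxy interaction factor
#'
#' Combines nucleic-acid type and treatment state into a single factor
#' (e.g. `DNA.pre`, `RNA.antibiotic`) so a rank test can probe their joint
#' structure without a modeled interaction term.
#'
#' @param a,b two factors of equal length.
#' @return a factor of pasted labels.
#' @export
interactionProxy <- function(a, b) {
  factor(paste(as.character(a), as.character(b), sep = "."))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control (via
#' \code{\link[stats]{p.adjust}}); output order matches input order.
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numbers in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance
#' (\code{\link[vegan]{adonis2}}) with sequential (Type I) sums of squares
#' in the order the terms are given, the adonis default. Supply either a
#' single grouping vector or a metadata data.frame plus a right-hand-side
#' formula such as `~ nucleic_acid * treatment`. The permutation p-value
#' is (1 + #\{permuted F >= observed\}) / (1 + permutations).
#'
#' @param dm a `dist` over the samples.
#' @param groups single grouping vector (alternative to `data`/`formula`).
#' @param data data.frame of predictors, rows aligned with `dm` labels.
#' @param formula right-hand-side formula over columns of `data`.
#' @param permutations number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutation stream.
#' @return data.frame, one row per term: `method`, `term`, `statistic`
#'   (pseudo-F), `df`, `r_squared`, `p_raw`.
#' @export
permanova <- function(dm, groups = NULL, data = NULL, formula = NULL,
                      permutations = 999, seed = NULL) {
  stopIfNotDist(dm)
  if (permutations < 99)
    stop("use at least 99 permutations")
  if (is.null(data)) {
    if (is.null(groups))
      stop("supply 'groups' or 'data' + 'formula'")
    data <- data.frame(group = factor(groups))
    formula <- ~ group
  }
  for (v in all.vars(formula)) {
    f <- data[[v]]
    if (is.character(f) || is.factor(f)) {
      f <- droplevels(factor(f))
      if (any(table(f) < 2L))
        stop("singleton level in factor '", v, "'")
      data[[v]] <- f
    }
  }
  fm <- stats::as.formula(paste("dm", paste(deparse(formula), collapse = "")))
  res <- withSeed(seed, muffleSmallPermSet(
    vegan::adonis2(fm, data = data, permutations = permutations,
                   by = "terms")))
  terms <- rownames(res)
  keep <- !(terms %in% c("Residual", "Total"))
  data.frame(method = "permanova",
             term = terms[keep],
             statistic = res$F[keep],
             df = res$Df[keep],
             r_squared = res$R2[keep],
             p_raw = res$`Pr(>F)`[keep],
             row.names = NULL)
}

#' Permutation test of multivariate dispersion
#'
#' Distances to group centroids in a principal-coordinate embedding
#' (\code{\link[vegan]{betadisper}}), with a permutation test of the
#' dispersion F. Used to verify a PERMANOVA group effect is a location,
#' not a spread, difference.
#'
#' @inheritParams permanova
#' @return one-row data.frame: `method`, `term`, `statistic` (F), `df`,
#'   `p_raw`.
#' @export
betaDispersionTest <- function(dm, groups, permutations = 999, seed = NULL) {
  stopIfNotDist(dm)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups")
  bd <- vegan::betadisper(dm, groups)
  pt <- withSeed(seed, muffleSmallPermSet(
    vegan::permutest(bd, permutations = permutations)))
  tab <- pt$tab
  data.frame(method = "beta_dispersion",
             term = "Groups",
             statistic = tab$F[1L],
             df = tab$Df[1L],
             p_raw = tab$`Pr(>F)`[1L],
             row.names = NULL)
}

#' Pairwise post hoc PERMANOVAs
#'
#' PERMANOVA on every pair of group levels, with Benjamini-Hochberg
#' adjustment across the k(k-1)/2 comparisons.
#'
#' @inheritParams permanova
#' @return data.frame, one row per level pair: `group1`, `group2`,
#'   `statistic`, `r_squared`, `p_raw`, `p_adjusted`.
#' @export
pairwisePermanova <- function(dm, groups, permutations = 999, seed = NULL) {
  stopIfNotDist(dm)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L)
    stop("need at least 2 groups")
  lv <- levels(groups)
  m <- as.matrix(dm)
  combs <- utils::combn(lv, 2L)
  seeds <- withSeed(seed, drawSeeds(ncol(combs)))
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    sel <- groups %in% combs[, i]
    sub <- stats::as.dist(m[sel, sel])
    r <- permanova(sub, groups = groups[sel], permutations = permutations,
                   seed = seeds[i])
    data.frame(group1 = combs[1L, i], group2 = combs[2L, i],
               statistic = r$statistic, r_squared = r$r_squared,
               p_raw = r$p_raw)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bhAdjust(out$p_raw)
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the vectorized distances (the classical Mantel
#' statistic), with significance from jointly permuting the rows and
#' columns of one matrix (\code{\link[vegan]{mantel}}). One-sided
#' (greater) by default, the usual convention for matrix association;
#' Spearman available via `method`.
#'
#' @param dm1,dm2 `dist` objects over identical labels in identical order.
#' @param permutations number of permutations (default 999).
#' @param seed integer seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return one-row data.frame: `method`, `statistic` (r), `permutations`,
#'   `p_raw`.
#' @export
mantelTest <- function(dm1, dm2, permutations = 999, seed = NULL,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopIfNotDist(dm1, "dm1")
  stopIfNotDist(dm2, "dm2")
  l1 <- attr(dm1, "Labels"); l2 <- attr(dm2, "Labels")
  if (attr(dm1, "Size") != attr(dm2, "Size") ||
      (!is.null(l1) && !is.null(l2) && !identical(l1, l2)))
    stop("distance matrices must cover identical labels in identical order")
  if (attr(dm1, "Size") < 4L)
    stop("Mantel test needs at least 4 objects")
  mt <- withSeed(seed, muffleSmallPermSet(
    vegan::mantel(dm1, dm2, method = method, permutations = permutations)))
  data.frame(method = paste0("mantel_", method),
             statistic = unname(mt$statistic),
             permutations = mt$permutations,
             p_raw = mt$signif,
             row.names = NULL)
}
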