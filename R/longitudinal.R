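#' Per-subject pre-to-post change in a scalar metric
#'
#' Computes post minus pre within subject for any per-(subject, timepoint)
#' scalar (proportion living, richness, entropy, evenness, ...). Subjects
#' missing either timepoint are skipped with a warning.
#'
#' @param df data.frame with columns `subject_id`, `timepoint`
#'   (`pre`/`post`) and `value`; extra label columns (e.g. `treatment`,
#'   `nucleic_acid`) are carried through from the post row.
#' @param metric name recorded in the output (default `"value"`).
#' @return data.frame: one row per subject with both timepoints, columns
#'   `subject_id`, carried labels, `metric`, `delta`.
#' @export
deltaMetric <- function(df, metric = "value") {
  need <- c("subject_id", "timepoint", "value")
  if (!all(need %in% names(df)))
    stop("need columns: ", paste(need, collapse = ", "))
  carry <- setdiff(names(df), c("timepoint", "value", "pair_id", "sample_id"))
  subjects <- unique(df$subject_id)
  rows <- lapply(subjects, function(s) {
    pre <- df[df$subject_id == s & df$timepoint == "pre", ]
    post <- df[df$subject_id == s & df$timepoint == "post", ]
    if (nrow(pre) != 1L || nrow(post) != 1L)
      return(NULL)
    out <- post[, carry, drop = FALSE]
    out$metric <- metric
    out$delta <- post$value - pre$value
    out
  })
  skipped <- subjects[vapply(rows, is.null, logical(1L))]
  if (length(skipped))
    warning("subjects missing a timepoint, skipped: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

#' Per-ASV change in relative abundance within subject
#'
#' Converts one nucleic acid's counts to per-sample proportions and takes
#' post minus pre within each subject. Because both timepoints' proportions
#' sum to one, each subject's deltas sum to zero across ASVs.
#'
#' @param ds a [PairedAmpliconSet-class] (typically the abundant dataset).
#' @param nucleicAcid `"DNA"` or `"RNA"` — which table to use.
#' @return matrix, subjects x ASVs, of proportion changes.
#' @export
relativeAbundanceDeltas <- function(ds, nucleicAcid = c("DNA", "RNA")) {
  nucleicAcid <- match.arg(nucleicAcid)
  stopifnot(is(ds, "PairedAmpliconSet"))
  ct <- if (nucleicAcid == "DNA") dnaCounts(ds) else rnaCounts(ds)
  sampleCol <- if (nucleicAcid == "DNA") "dna_sample" else "rna_sample"
  m <- counts(ct)
  if (any(rowSums(m) == 0))
    stop("all-zero samples in the ", nucleicAcid, " table")
  prop <- m / rowSums(m)
  p <- samplePairs(ds)
  subjects <- intersect(p$subject_id[p$timepoint == "pre"],
                        p$subject_id[p$timepoint == "post"])
  out <- t(vapply(subjects, function(s) {
    preS <- p[[sampleCol]][p$subject_id == s & p$timepoint == "pre"]
    postS <- p[[sampleCol]][p$subject_id == s & p$timepoint == "post"]
    prop[postS, ] - prop[preS, ]
  }, numeric(ncol(prop))))
  rownames(out) <- subjects
  colnames(out) <- asvIDs(ds)
  out
}

#' Paired pre/post beta-diversity distance per subject
#'
#' Extracts, for each subject, the distance between its pre and post
#' samples from a sample-level distance matrix.
#'
#' @param dm a `dist` whose labels include every referenced sample.
#' @param pre,post named character vectors (names = subject ids) of the
#'   pre- and post-timepoint sample ids.
#' @return data.frame: `subject_id`, `distance`.
#' @export
pairedBetaDistance <- function(dm, pre, post) {
  stopIfNotDist(dm)
  subjects <- intersect(names(pre), names(post))
  m <- as.matrix(dm)
  missing <- setdiff(c(pre[subjects], post[subjects]), rownames(m))
  if (length(missing))
    stop("samples absent from the distance matrix: ",
         paste(missing, collapse = ", "))
  data.frame(subject_id = subjects,
             distance = m[cbind(pre[subjects], post[subjects])],
             stringsAsFactors = FALSE, row.names = NULL)
}
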