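#' Read an ASV count table
#'
#' Reads a feature table in either a TSV dialect (header row of ids, first
#' column the other axis' ids) or BIOM JSON (format 1.0, via
#' \pkg{biomformat}). Counts must be non-negative and exactly integral;
#' anything else is a validation error naming the offending entries.
#'
#' @param path file to read.
#' @param format `"tsv"` or `"biom_json"`.
#' @param orientation for TSV only: `"asv_rows"` (default; rows are ASVs,
#'   columns samples — the common denoiser export) or `"sample_rows"`.
#' @return a [CountTable-class] (samples x ASVs internally).
#' @export
readCountTable <- function(path, format = c("tsv", "biom_json"),
                           orientation = c("asv_rows", "sample_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (format == "biom_json") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")   # features x samples
    return(CountTable(checkCountMatrix(m, path), orientation = "asv_rows"))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("malformed TSV count table (need an id column plus counts): ", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    loc <- if (nrow(bad)) paste0("row ", bad[1L, 1L], ", column ",
                                 colnames(m)[bad[1L, 2L]])
           else "unknown position"
    stop("non-numeric count at ", loc, " of ", path)
  }
  rownames(m) <- ids
  CountTable(checkCountMatrix(m, path), orientation = orientation)
}

# Validation shared by both dialects; errors name the first offending cell.
checkCountMatrix <- function(m, path) {
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing count at (", rownames(m)[bad[1L]], ", ",
         colnames(m)[bad[2L]], ") in ", path)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at (", rownames(m)[bad[1L]], ", ",
         colnames(m)[bad[2L]], ") in ", path)
  }
  if (any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1L, ]
    stop("non-integral count at (", rownames(m)[bad[1L]], ", ",
         colnames(m)[bad[2L]], ") in ", path)
  }
  storage.mode(m) <- "integer"
  m
}

#' Write an ASV count table
#'
#' @param ct a [CountTable-class].
#' @param path output file.
#' @param format `"tsv"` or `"biom_json"`.
#' @param orientation TSV row axis, as in [readCountTable()].
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(ct, path, format = c("tsv", "biom_json"),
                            orientation = c("asv_rows", "sample_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  stopifnot(is(ct, "CountTable"))
  if (format == "biom_json") {
    b <- biomformat::make_biom(t(counts(ct)))    # biom wants features x samples
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  m <- counts(ct)
  if (orientation == "asv_rows") {
    df <- data.frame(asv_id = colnames(m), t(m), check.names = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  }
  writeTSV(df, path)
}

#' Read and validate the sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `subject_id`, `timepoint`
#' (`pre`/`post`), `treatment` (`control`/`antibiotic`) and `nucleic_acid`
#' (`DNA`/`RNA`). The combination (subject, timepoint, nucleic acid) must
#' be unique — one swab event yields exactly one DNA and one RNA sample.
#'
#' @param path TSV file, or a data.frame already in memory.
#' @return validated data.frame with factor-coded enums.
#' @export
readSampleMetadata <- function(path) {
  meta <- if (is.data.frame(path)) path
          else utils::read.delim(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "timepoint", "treatment", "nucleic_acid")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  meta <- meta[, need]
  meta$sample_id <- as.character(meta$sample_id)
  meta$subject_id <- as.character(meta$subject_id)
  if (!all(meta$timepoint %in% c("pre", "post")))
    stop("timepoint must be 'pre' or 'post'")
  if (!all(meta$treatment %in% c("control", "antibiotic")))
    stop("treatment must be 'control' or 'antibiotic'")
  if (!all(meta$nucleic_acid %in% c("DNA", "RNA")))
    stop("nucleic_acid must be 'DNA' or 'RNA'")
  meta$timepoint <- factor(meta$timepoint, levels = c("pre", "post"))
  meta$treatment <- factor(meta$treatment, levels = c("control", "antibiotic"))
  meta$nucleic_acid <- factor(meta$nucleic_acid, levels = c("DNA", "RNA"))
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample_id in metadata")
  key <- paste(meta$subject_id, meta$timepoint, meta$nucleic_acid)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)]
    stop("duplicate (subject, timepoint, nucleic_acid): ",
         paste(unique(dup), collapse = "; "))
  }
  meta
}

#' Read a taxonomy map
#'
#' TSV with columns `asv_id` and `lineage` (semicolon-delimited ranks,
#' domain down to genus). Returns a named list of rank vectors.
#'
#' @param path TSV file.
#' @return named list: asv_id -> character vector of lineage ranks.
#' @export
readTaxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("asv_id", "lineage") %in% names(df)))
    stop("taxonomy table needs columns 'asv_id' and 'lineage'")
  out <- lapply(strsplit(df$lineage, ";", fixed = TRUE), trimws)
  names(out) <- df$asv_id
  out
}

#' Align DNA and RNA tables into a PairedAmpliconSet
#'
#' Unions the ASV lists of both tables (missing ASVs filled with zero
#' counts — absence, never missing data), checks that every sample has a
#' metadata row and that each (subject, timepoint) contributes exactly one
#' DNA and one RNA sample, and enumerates the pairs in deterministic order
#' (subject id, then pre before post).
#'
#' @param dna,rna [CountTable-class] objects for the two nucleic acids.
#' @param meta sample metadata (path, or data.frame accepted by
#'   [readSampleMetadata()]).
#' @return a [PairedAmpliconSet-class].
#' @export
buildPairedDataset <- function(dna, rna, meta) {
  stopifnot(is(dna, "CountTable"), is(rna, "CountTable"))
  meta <- readSampleMetadata(meta)

  allSamples <- c(sampleIDs(dna), sampleIDs(rna))
  missingMeta <- setdiff(allSamples, meta$sample_id)
  if (length(missingMeta))
    stop("samples without metadata: ", paste(missingMeta, collapse = ", "))

  metaD <- meta[meta$nucleic_acid == "DNA" & meta$sample_id %in% sampleIDs(dna), ]
  metaR <- meta[meta$nucleic_acid == "RNA" & meta$sample_id %in% sampleIDs(rna), ]
  if (!all(sampleIDs(dna) %in% metaD$sample_id))
    stop("DNA table contains samples not labelled nucleic_acid=DNA in metadata")
  if (!all(sampleIDs(rna) %in% metaR$sample_id))
    stop("RNA table contains samples not labelled nucleic_acid=RNA in metadata")

  keyD <- paste(metaD$subject_id, metaD$timepoint, sep = "\r")
  keyR <- paste(metaR$subject_id, metaR$timepoint, sep = "\r")
  orphanR <- metaR$sample_id[!(keyR %in% keyD)]
  orphanD <- metaD$sample_id[!(keyD %in% keyR)]
  if (length(orphanR) || length(orphanD))
    stop("unpaired samples: ",
         paste(c(orphanD, orphanR), collapse = ", "))

  # union ASVs in order of first appearance (DNA first), zero-fill
  asvs <- union(asvIDs(dna), asvIDs(rna))
  expand <- function(ct) {
    m <- matrix(0L, nrow = nSamples(ct), ncol = length(asvs),
                dimnames = list(sampleIDs(ct), asvs))
    m[, asvIDs(ct)] <- counts(ct)
    new("CountTable", counts = m)
  }
  dna2 <- expand(dna)
  rna2 <- expand(rna)

  metaD <- metaD[order(metaD$subject_id, metaD$timepoint), ]
  keyD <- paste(metaD$subject_id, metaD$timepoint, sep = "\r")
  keyR <- paste(metaR$subject_id, metaR$timepoint, sep = "\r")
  pairs <- data.frame(
    subject_id = metaD$subject_id,
    timepoint = metaD$timepoint,
    treatment = metaD$treatment,
    dna_sample = metaD$sample_id,
    rna_sample = metaR$sample_id[match(keyD, keyR)],
    stringsAsFactors = FALSE)
  pairs$pair_id <- paste(pairs$subject_id, pairs$timepoint, sep = "_")
  rownames(pairs) <- NULL

  new("PairedAmpliconSet", dna = dna2, rna = rna2, pairs = pairs,
      metadata = meta)
}
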