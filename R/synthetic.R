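#' Scenario configuration for the synthetic paired-community generator
#'
#' Defines a two-timepoint, two-arm study of paired DNA/RNA amplicon
#' samples with known latent structure. Defaults emulate a small
#' low-biomass ocular study: 7 subjects (3 control, 4 antibiotic) swabbed
#' pre and post treatment, an ASV pool of several hundred taxa most of
#' which are detectable only as relic DNA, per-sample read depths in the
#' tens of thousands, and a bacteriostatic treatment that suppresses the
#' activity of susceptible taxa without killing them.
#'
#' @param n_subjects number of subjects (default 7).
#' @param n_control subjects in the control arm (default 3; the rest are
#'   antibiotic-treated).
#' @param n_asvs size of the ASV pool (default 800).
#' @param frac_dead fraction of ASVs present only as relic DNA from dead
#'   cells (default 0.55).
#' @param frac_transient fraction of ASVs that are transient, DNA-only
#'   contaminants whose mass is redrawn at each timepoint (default 0.08).
#' @param frac_dormant fraction of living ASVs in the low-activity
#'   (dormant) state (default 0.3).
#' @param a_hi,a_lo activity level of active vs dormant living ASVs, in
#'   [0, 1] (defaults 0.8 and 0.05).
#' @param rrna_factor mean rRNA copies per active cell (default 1, which
#'   makes RNA:DNA thresholds directly interpretable).
#' @param rrna_sd lognormal sd of per-ASV rRNA factors (default 0 =
#'   homogeneous; positive values model copy-number heterogeneity).
#' @param gene_copies mean 16S gene copies per genome (default 1).
#' @param gene_copies_sd lognormal sd of per-ASV gene copies (default 0).
#' @param frac_susceptible fraction of living ASVs susceptible to the
#'   treatment (default 0.3).
#' @param treatment_f activity multiplier applied to susceptible ASVs at
#'   the post timepoint, in (0, 1] (default 0.1).
#' @param treatment_mode `"bacteriostatic"` (reduces activity, preserves
#'   abundance — the default) or `"bactericidal"` (reduces living
#'   abundance).
#' @param drift_sd lognormal sd of the between-timepoint drift applied to
#'   every living abundance in every subject (default 0.5, emulating the
#'   strong temporal turnover typical of such data; 0 disables drift).
#' @param abund_meanlog,abund_sdlog lognormal parameters of the latent
#'   absolute abundances (defaults 0 and 2: heavy-tailed).
#' @param dna_depth_range,rna_depth_range integer range the per-sample
#'   read depth is drawn from (defaults 19821-58962 and 28721-83021).
#' @param seed integer seed; every draw the generator makes descends from
#'   it.
#' @return a validated list of class `ScenarioConfig`.
#' @export
scenarioConfig <- function(n_subjects = 7, n_control = 3, n_asvs = 800,
                           frac_dead = 0.55, frac_transient = 0.08,
                           frac_dormant = 0.3, a_hi = 0.8, a_lo = 0.05,
                           rrna_factor = 1, rrna_sd = 0,
                           gene_copies = 1, gene_copies_sd = 0,
                           frac_susceptible = 0.3, treatment_f = 0.1,
                           treatment_mode = c("bacteriostatic", "bactericidal"),
                           drift_sd = 0.5,
                           abund_meanlog = 0, abund_sdlog = 2,
                           dna_depth_range = c(19821, 58962),
                           rna_depth_range = c(28721, 83021),
                           seed = 1) {
  treatment_mode <- match.arg(treatment_mode)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_control = as.integer(n_control), n_asvs = as.integer(n_asvs),
              frac_dead = frac_dead, frac_transient = frac_transient,
              frac_dormant = frac_dormant, a_hi = a_hi, a_lo = a_lo,
              rrna_factor = rrna_factor, rrna_sd = rrna_sd,
              gene_copies = gene_copies, gene_copies_sd = gene_copies_sd,
              frac_susceptible = frac_susceptible, treatment_f = treatment_f,
              treatment_mode = treatment_mode, drift_sd = drift_sd,
              abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
              dna_depth_range = as.integer(dna_depth_range),
              rna_depth_range = as.integer(rna_depth_range),
              seed = as.integer(seed))
  fr <- c(cfg$frac_dead, cfg$frac_transient, cfg$frac_dormant,
          cfg$frac_susceptible)
  if (any(fr < 0 | fr > 1))
    stop("fractions must lie in [0, 1]")
  if (cfg$frac_dead + cfg$frac_transient > 1)
    stop("frac_dead + frac_transient exceeds 1")
  if (cfg$n_control < 0 || cfg$n_control > cfg$n_subjects)
    stop("n_control must be between 0 and n_subjects")
  if (cfg$a_hi < 0 || cfg$a_hi > 1 || cfg$a_lo < 0 || cfg$a_lo > 1)
    stop("activity levels must lie in [0, 1]")
  if (cfg$treatment_f <= 0 || cfg$treatment_f > 1)
    stop("treatment_f must lie in (0, 1]")
  if (any(cfg$dna_depth_range < 1) || any(cfg$rna_depth_range < 1))
    stop("depths must be positive")
  if (cfg$rrna_factor <= 0 || cfg$gene_copies < 1)
    stop("rrna_factor must be > 0 and gene_copies >= 1")
  class(cfg) <- "ScenarioConfig"
  cfg
}

#' Generate the latent per-subject community truth
#'
#' Assigns each ASV a role (living, dead-only, transient) and, for living
#' taxa, a dormancy state, susceptibility flag and per-cell rRNA/gene-copy
#' factors — shared across subjects, as real taxa share their biology.
#' Per-subject absolute abundances are drawn from a heavy-tailed
#' lognormal. Dead-only ASVs carry relic DNA but no living cells;
#' transient ASVs likewise (flagged separately, and their mass is redrawn
#' per timepoint by [generateStudy()]). Deterministic given the seed.
#'
#' @param cfg a [scenarioConfig()].
#' @param seed seed (defaults to `cfg$seed`).
#' @return named list (one data.frame per subject) of class
#'   `SyntheticTruth`, with columns `asv_id`, `living_abundance`,
#'   `relic_abundance`, `activity`, `rrna_factor`, `gene_copies`,
#'   `susceptible`, `transient`; the config is attached as attribute
#'   `"config"`.
#' @export
generateTruth <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  withSeed(seed, {
    n <- cfg$n_asvs
    asv <- sprintf("ASV_%04d", seq_len(n))
    role <- sample(c("dead", "transient", "living"), n, replace = TRUE,
                   prob = c(cfg$frac_dead, cfg$frac_transient,
                            1 - cfg$frac_dead - cfg$frac_transient))
    living <- role == "living"
    dormant <- living & stats::runif(n) < cfg$frac_dormant
    susceptible <- living & stats::runif(n) < cfg$frac_susceptible
    rrna <- if (cfg$rrna_sd > 0)
      stats::rlnorm(n, log(cfg$rrna_factor), cfg$rrna_sd)
    else rep(cfg$rrna_factor, n)
    gcp <- if (cfg$gene_copies_sd > 0)
      pmax(1, stats::rlnorm(n, log(cfg$gene_copies), cfg$gene_copies_sd))
    else rep(cfg$gene_copies, n)
    activity <- ifelse(living, ifelse(dormant, cfg$a_lo, cfg$a_hi), 0)

    subjects <- sprintf("S%d", seq_len(cfg$n_subjects))
    out <- lapply(subjects, function(s) {
      liveAb <- ifelse(living,
                       stats::rlnorm(n, cfg$abund_meanlog, cfg$abund_sdlog), 0)
      relicAb <- ifelse(living, 0,
                        stats::rlnorm(n, cfg$abund_meanlog, cfg$abund_sdlog))
      data.frame(asv_id = asv, living_abundance = liveAb,
                 relic_abundance = relicAb, activity = activity,
                 rrna_factor = rrna, gene_copies = gcp,
                 susceptible = susceptible, transient = role == "transient",
                 stringsAsFactors = FALSE)
    })
    names(out) <- subjects
    attr(out, "config") <- cfg
    class(out) <- "SyntheticTruth"
    out
  })
}

#' Apply the treatment effect to one subject's truth
#'
#' Bacteriostatic semantics (default): susceptible ASVs' activity is
#' multiplied by `f`, living abundance untouched — cells stop
#' transcribing, they do not die. Bactericidal mode multiplies the living
#' abundance instead.
#'
#' @param truth one subject's truth data.frame (an element of
#'   [generateTruth()]).
#' @param f multiplier in (0, 1]; `f = 1` is the identity.
#' @param mode `"bacteriostatic"` (default) or `"bactericidal"`.
#' @return modified truth data.frame.
#' @export
applyTreatment <- function(truth, f,
                           mode = c("bacteriostatic", "bactericidal")) {
  mode <- match.arg(mode)
  if (f <= 0 || f > 1)
    stop("'f' must lie in (0, 1]")
  s <- truth$susceptible
  if (mode == "bacteriostatic") {
    truth$activity[s] <- truth$activity[s] * f
  } else {
    truth$living_abundance[s] <- truth$living_abundance[s] * f
  }
  truth
}

#' Expected read proportions under the generative model
#'
#' DNA read probability of an ASV is proportional to
#' (living + relic abundance) x gene copies; RNA read probability to
#' living abundance x activity x rRNA factor. These are the multinomial
#' probabilities [simulatePair()] samples from.
#'
#' @param truth one subject's truth data.frame.
#' @param nucleicAcid `"DNA"` or `"RNA"`.
#' @return named numeric vector of proportions summing to 1.
#' @export
expectedReadProportions <- function(truth, nucleicAcid = c("DNA", "RNA")) {
  nucleicAcid <- match.arg(nucleicAcid)
  w <- if (nucleicAcid == "DNA")
    (truth$living_abundance + truth$relic_abundance) * truth$gene_copies
  else
    truth$living_abundance * truth$activity * truth$rrna_factor
  if (sum(w) <= 0)
    stop("all-zero ", nucleicAcid, " probability vector")
  stats::setNames(w / sum(w), truth$asv_id)
}

#' Simulate one paired (DNA, RNA) sample
#'
#' Multinomial draws at the given depths from the model probabilities
#' (see [expectedReadProportions()]). Deterministic given the seed.
#'
#' @param truth one subject's truth data.frame.
#' @param dnaDepth,rnaDepth reads to draw for each nucleic acid.
#' @param seed integer seed.
#' @return list with integer count vectors `dna` and `rna`, named by ASV.
#' @export
simulatePair <- function(truth, dnaDepth, rnaDepth, seed = NULL) {
  pD <- expectedReadProportions(truth, "DNA")
  pR <- expectedReadProportions(truth, "RNA")
  withSeed(seed, {
    dna <- as.integer(stats::rmultinom(1L, dnaDepth, pD))
    rna <- as.integer(stats::rmultinom(1L, rnaDepth, pR))
    list(dna = stats::setNames(dna, truth$asv_id),
         rna = stats::setNames(rna, truth$asv_id))
  })
}

#' Generate a complete two-timepoint, two-arm paired study
#'
#' Mirrors the default design: `n_subjects` subjects swabbed pre and post,
#' the first `n_control` assigned to the control arm and the rest to the
#' antibiotic arm, each swab event yielding one DNA and one RNA sample
#' (so 7 subjects give 14 swab events and 28 sample vectors). Between
#' timepoints every subject's living abundances drift (lognormal,
#' `drift_sd`), transient contaminant mass is redrawn, and susceptible
#' ASVs in antibiotic subjects receive the treatment effect. Byte-identical
#' on rerun with the same config and seed.
#'
#' @param cfg a [scenarioConfig()].
#' @return list: `dataset` (a [PairedAmpliconSet-class]), `metadata`
#'   (per-sample data.frame), `truth` (long data.frame of the latent
#'   state per subject and timepoint), `config`.
#' @export
generateStudy <- function(cfg) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  withSeed(cfg$seed, {
    seeds <- drawSeeds(4L)
    truthPre <- generateTruth(cfg, seed = seeds[1L])
    subjects <- names(truthPre)
    arm <- stats::setNames(
      rep(c("control", "antibiotic"),
          c(cfg$n_control, cfg$n_subjects - cfg$n_control)), subjects)

    # post-timepoint truth: drift + fresh transients + treatment
    truthPost <- withSeed(seeds[2L], lapply(subjects, function(s) {
      tr <- truthPre[[s]]
      liv <- tr$living_abundance > 0
      if (cfg$drift_sd > 0)
        tr$living_abundance[liv] <- tr$living_abundance[liv] *
          stats::rlnorm(sum(liv), 0, cfg$drift_sd)
      tt <- tr$transient
      tr$relic_abundance[tt] <-
        stats::rlnorm(sum(tt), cfg$abund_meanlog, cfg$abund_sdlog)
      if (arm[[s]] == "antibiotic")
        tr <- applyTreatment(tr, cfg$treatment_f, cfg$treatment_mode)
      tr
    }))
    names(truthPost) <- subjects

    events <- expand.grid(subject_id = subjects, timepoint = c("pre", "post"),
                          stringsAsFactors = FALSE)
    events <- events[order(events$subject_id,
                           match(events$timepoint, c("pre", "post"))), ]
    nEv <- nrow(events)
    drawDepths <- function(range) {
      # guard the scalar-x behaviour of sample() when the range collapses
      pool <- seq(range[1L], range[2L])
      pool[sample.int(length(pool), nEv, replace = TRUE)]
    }
    depths <- withSeed(seeds[3L], list(dna = drawDepths(cfg$dna_depth_range),
                                       rna = drawDepths(cfg$rna_depth_range)))
    evSeeds <- withSeed(seeds[4L], drawSeeds(nEv))

    asv <- truthPre[[1L]]$asv_id
    dnaM <- matrix(0L, nEv, length(asv))
    rnaM <- matrix(0L, nEv, length(asv))
    dnaIDs <- character(nEv); rnaIDs <- character(nEv)
    truthRows <- vector("list", nEv)
    for (k in seq_len(nEv)) {
      s <- events$subject_id[k]; tp <- events$timepoint[k]
      tr <- if (tp == "pre") truthPre[[s]] else truthPost[[s]]
      sim <- simulatePair(tr, depths$dna[k], depths$rna[k], seed = evSeeds[k])
      dnaM[k, ] <- sim$dna
      rnaM[k, ] <- sim$rna
      dnaIDs[k] <- paste(s, tp, "DNA", sep = "_")
      rnaIDs[k] <- paste(s, tp, "RNA", sep = "_")
      truthRows[[k]] <- cbind(subject_id = s, timepoint = tp,
                              treatment = arm[[s]], tr,
                              stringsAsFactors = FALSE)
    }
    dimnames(dnaM) <- list(dnaIDs, asv)
    dimnames(rnaM) <- list(rnaIDs, asv)

    metadata <- rbind(
      data.frame(sample_id = dnaIDs, subject_id = events$subject_id,
                 timepoint = events$timepoint,
                 treatment = arm[events$subject_id],
                 nucleic_acid = "DNA", stringsAsFactors = FALSE),
      data.frame(sample_id = rnaIDs, subject_id = events$subject_id,
                 timepoint = events$timepoint,
                 treatment = arm[events$subject_id],
                 nucleic_acid = "RNA", stringsAsFactors = FALSE))
    rownames(metadata) <- NULL

    ds <- buildPairedDataset(CountTable(dnaM), CountTable(rnaM), metadata)
    truth <- do.call(rbind, truthRows)
    rownames(truth) <- NULL
    list(dataset = ds, metadata = metadata, truth = truth, config = cfg)
  })
}

#' Write a generated study to disk
#'
#' Emits the count tables in the TSV dialect (ASVs as rows), the sample
#' metadata, the latent-truth sidecar and the scenario config (YAML), all
#' plain text.
#'
#' @param study result of [generateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCountTable(dnaCounts(study$dataset), file.path(dir, "dna_counts.tsv"),
                  format = "tsv", orientation = "asv_rows")
  writeCountTable(rnaCounts(study$dataset), file.path(dir, "rna_counts.tsv"),
                  format = "tsv", orientation = "asv_rows")
  writeTSV(study$metadata, file.path(dir, "metadata.tsv"))
  writeTSV(study$truth, file.path(dir, "truth.tsv"))
  cfg <- study$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "scenario.yaml"))
  invisible(dir)
}
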