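#' Pipeline configuration
#'
#' Materializes every filter and test setting the analysis uses, so a run
#' is fully described by its config and seed. Written to the provenance
#' log before any computation.
#'
#' @param dna,rna paths to the DNA and RNA count tables (TSV, ASVs as
#'   rows), or [CountTable-class] objects.
#' @param metadata path to the sample metadata TSV, or a data.frame.
#' @param abundance_threshold per-sample fraction an ASV must reach in at
#'   least one sample to count as abundant (default 0.01).
#' @param rarefaction_depth `"auto"` (the lowest read depth across all
#'   samples) or an integer.
#' @param seed integer seed driving every random stage.
#' @param thresholds RNA:DNA activity cut-offs (default `c(0.5, 1, 2)`).
#' @param permutations permutations for PERMANOVA/dispersion/Mantel
#'   (default 999).
#' @param phantom_scope `"pair"` or `"global"` (see
#'   [removePhantomReads()]).
#' @param pseudocount_mode `"all"` or `"zeros"` (see
#'   [pseudocountAdjust()]).
#' @param strict_threshold use `>` instead of `>=` at activity boundaries.
#' @param absent_policy `"undefined"` or `"inactive"` (see [shiftCode()]).
#' @param shift_undefined `"zero"` or `"drop"` (see [shiftDistance()]).
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(dna, rna, metadata,
                           abundance_threshold = 0.01,
                           rarefaction_depth = "auto",
                           seed = 1,
                           thresholds = c(0.5, 1, 2),
                           permutations = 999,
                           phantom_scope = c("pair", "global"),
                           pseudocount_mode = c("all", "zeros"),
                           strict_threshold = FALSE,
                           absent_policy = c("undefined", "inactive"),
                           shift_undefined = c("zero", "drop")) {
  cfg <- list(dna = dna, rna = rna, metadata = metadata,
              abundance_threshold = abundance_threshold,
              rarefaction_depth = rarefaction_depth,
              seed = as.integer(seed),
              thresholds = sort(thresholds),
              permutations = as.integer(permutations),
              phantom_scope = match.arg(phantom_scope),
              pseudocount_mode = match.arg(pseudocount_mode),
              strict_threshold = isTRUE(strict_threshold),
              absent_policy = match.arg(absent_policy),
              shift_undefined = match.arg(shift_undefined))
  class(cfg) <- "PipelineConfig"
  cfg
}

loadTable <- function(x) {
  if (is(x, "CountTable")) x else readCountTable(x, format = "tsv")
}

#' Run the full paired-amplicon analysis
#'
#' Fixed stage order: load and pair the tables; remove phantom reads;
#' proportion living on the full dataset; abundance screen; proportion
#' living on the abundant dataset; rarefy; alpha diversity (rarefied);
#' Bray-Curtis (proportional) and Jaccard (binary) beta diversity with
#' PERMANOVA (nucleic acid, treatment state, interaction), dispersion
#' checks, pairwise post hocs and a DNA-vs-RNA Mantel test per metric;
#' paired pre/post deltas with Kruskal-Wallis tests (BH-adjusted);
#' pseudocount adjustment; RNA:DNA ratios; activity classification at
#' each threshold; shift coding and shift distance matrices; Mantel tests
#' between thresholds. All tabular outputs are TSV; the provenance log
#' (JSON) records config, seed and stage order. Two runs with the same
#' config and seed produce byte-identical tables.
#'
#' @param cfg a [pipelineConfig()].
#' @param outdir directory for results (created if needed).
#' @return invisibly, a list with the main intermediate objects and
#'   result tables.
#' @export
runAnalysis <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stageSeeds <- withSeed(cfg$seed, drawSeeds(8L))
  reports <- list()
  stages <- character()
  stage <- function(name) stages[[length(stages) + 1L]] <<- name

  withStage <- function(name, expr) {
    stage(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- load & pair -----------------------------------------------------
  ds <- withStage("load_pair", {
    buildPairedDataset(loadTable(cfg$dna), loadTable(cfg$rna), cfg$metadata)
  })

  # --- phantom removal -------------------------------------------------
  ph <- withStage("phantom_removal",
                  removePhantomReads(ds, scope = cfg$phantom_scope))
  reports$phantom <- ph$report
  dsFull <- ph$dataset

  plFull <- withStage("proportion_living_full", proportionLiving(dsFull))
  writeTSV(plFull, file.path(outdir, "proportion_living_full.tsv"))

  # --- abundance screen ------------------------------------------------
  ab <- withStage("abundance_filter",
                  abundanceFilter(dsFull, cfg$abundance_threshold))
  reports$abundance <- ab$report
  dsAb <- ab$dataset

  plAb <- withStage("proportion_living_abundant", proportionLiving(dsAb))
  writeTSV(plAb, file.path(outdir, "proportion_living_abundant.tsv"))

  # proportion-living group comparison (treatment state) on both datasets
  kwPL <- withStage("proportion_living_tests", {
    rows <- lapply(list(full = plFull, abundant = plAb), function(pl) {
      st <- treatmentState(pl$timepoint, pl$treatment)
      cbind(response = "proportion_living", kruskalWallis(pl$proportion_living, st))
    })
    out <- do.call(rbind, rows)
    out$dataset <- names(rows)
    out$p_adjusted <- bhAdjust(out$p_raw)
    out
  })
  writeTSV(kwPL, file.path(outdir, "proportion_living_tests.tsv"))

  # --- rarefaction -----------------------------------------------------
  rar <- withStage("rarefaction",
                   rarefyDataset(dsAb, cfg$rarefaction_depth, stageSeeds[1L]))
  dsRar <- rar$dataset

  # --- alpha diversity (rarefied) + KW tests ---------------------------
  meta <- sampleData(dsRar)
  alphaTab <- withStage("alpha_diversity", {
    a <- rbind(alphaDiversity(dnaCounts(dsRar)), alphaDiversity(rnaCounts(dsRar)))
    merge(a, meta, by = "sample_id", sort = TRUE)
  })
  writeTSV(alphaTab, file.path(outdir, "alpha_diversity.tsv"))

  alphaTests <- withStage("alpha_tests", {
    st <- treatmentState(alphaTab$timepoint, alphaTab$treatment)
    proxy <- interactionProxy(alphaTab$nucleic_acid, st)
    rows <- list()
    for (metric in c("richness", "shannon", "pielou")) {
      v <- alphaTab[[metric]]
      ok <- !is.na(v)
      rows[[paste(metric, "nucleic")]] <-
        cbind(response = metric, predictor = "nucleic_acid",
              kruskalWallis(v[ok], alphaTab$nucleic_acid[ok]))
      rows[[paste(metric, "treat")]] <-
        cbind(response = metric, predictor = "treatment",
              kruskalWallis(v[ok], st[ok]))
      rows[[paste(metric, "proxy")]] <-
        cbind(response = metric, predictor = "interaction",
              kruskalWallis(v[ok], proxy[ok]))
    }
    out <- do.call(rbind, rows)
    out$p_adjusted <- bhAdjust(out$p_raw)
    rownames(out) <- NULL
    out
  })

  # --- beta diversity + PERMANOVA block --------------------------------
  betaBlock <- withStage("beta_diversity", {
    # one table stacking both nucleic acids; labels are sample ids
    allM <- rbind(counts(dnaCounts(dsAb)), counts(rnaCounts(dsAb)))
    ctAll <- new("CountTable", counts = allM)
    metaAll <- meta[match(rownames(allM), meta$sample_id), ]
    st <- treatmentState(metaAll$timepoint, metaAll$treatment)
    pred <- data.frame(nucleic_acid = metaAll$nucleic_acid,
                       treat_state = st)
    out <- list()
    mseeds <- withSeed(stageSeeds[2L], drawSeeds(8L))
    i <- 0L
    for (metric in c("jaccard", "bray_curtis")) {
      dmAll <- betaDiversity(ctAll, metric)
      pmv <- permanova(dmAll, data = pred,
                       formula = ~ nucleic_acid * treat_state,
                       permutations = cfg$permutations,
                       seed = mseeds[i + 1L])
      disp <- rbind(
        cbind(factor = "nucleic_acid",
              betaDispersionTest(dmAll, pred$nucleic_acid,
                                 cfg$permutations, mseeds[i + 2L])),
        cbind(factor = "treat_state",
              betaDispersionTest(dmAll, pred$treat_state,
                                 cfg$permutations, mseeds[i + 3L])))
      pw <- pairwisePermanova(dmAll, pred$treat_state,
                              cfg$permutations, mseeds[i + 4L])
      # per-nucleic-acid distance over pair ids, for Mantel DNA vs RNA
      p <- samplePairs(dsAb)
      mkDist <- function(sampleCol) {
        m <- allM[p[[sampleCol]], , drop = FALSE]
        rownames(m) <- p$pair_id
        betaDiversity(new("CountTable", counts = m), metric)
      }
      dmD <- mkDist("dna_sample"); dmR <- mkDist("rna_sample")
      mant <- mantelTest(dmD, dmR, cfg$permutations, seed = mseeds[i + 1L])
      out[[metric]] <- list(dm = dmAll, dmDNA = dmD, dmRNA = dmR,
                            permanova = pmv, dispersion = disp,
                            pairwise = pw, mantel = mant)
      i <- i + 4L
    }
    out
  })
  for (metric in names(betaBlock)) {
    writeDistanceMatrix(betaBlock[[metric]]$dm,
                        file.path(outdir, paste0("beta_", metric, ".tsv")))
    writeTSV(betaBlock[[metric]]$pairwise,
             file.path(outdir, paste0("pairwise_permanova_", metric, ".tsv")))
  }

  # --- NMDS (plotting coordinates only) --------------------------------
  nmdsTabs <- withStage("nmds", lapply(betaBlock, function(b) {
    fit <- runNMDS(b$dm, k = 2)
    data.frame(sample_id = rownames(fit$points), fit$points,
               stress = fit$stress, stringsAsFactors = FALSE)
  }))
  for (metric in names(nmdsTabs))
    writeTSV(nmdsTabs[[metric]],
             file.path(outdir, paste0("nmds_", metric, ".tsv")))

  # --- Table-1-shaped summary ------------------------------------------
  mainTable <- withStage("main_table", {
    rows <- list()
    for (metric in c("richness", "shannon", "pielou")) {
      sub <- alphaTests[alphaTests$response == metric, ]
      rows[[metric]] <- data.frame(
        response = metric, predictor = sub$predictor,
        statistic = sub$statistic, r_squared = NA_real_,
        p_adjusted = sub$p_adjusted)
    }
    for (metric in names(betaBlock)) {
      pmv <- betaBlock[[metric]]$permanova
      padj <- bhAdjust(pmv$p_raw)
      rows[[metric]] <- data.frame(
        response = metric,
        predictor = c("nucleic_acid", "treatment", "interaction"),
        statistic = pmv$statistic, r_squared = pmv$r_squared,
        p_adjusted = padj)
      mt <- betaBlock[[metric]]$mantel
      rows[[paste0(metric, "_mantel")]] <- data.frame(
        response = metric, predictor = "mantel_dna_vs_rna",
        statistic = mt$statistic, r_squared = NA_real_,
        p_adjusted = mt$p_raw)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
  writeTSV(mainTable, file.path(outdir, "main_results.tsv"))

  # --- paired pre/post deltas + tests ----------------------------------
  deltas <- withStage("deltas", {
    rows <- list()
    # proportion living (per dataset flavour)
    for (nm in c("full", "abundant")) {
      pl <- if (nm == "full") plFull else plAb
      d <- deltaMetric(data.frame(subject_id = pl$subject_id,
                                  timepoint = pl$timepoint,
                                  treatment = pl$treatment,
                                  value = pl$proportion_living),
                       metric = paste0("proportion_living_", nm))
      d$nucleic_acid <- "paired"
      rows[[nm]] <- d
    }
    # alpha metrics within nucleic acid
    for (na in c("DNA", "RNA")) {
      sub <- alphaTab[alphaTab$nucleic_acid == na, ]
      for (metric in c("richness", "shannon", "pielou")) {
        d <- deltaMetric(data.frame(subject_id = sub$subject_id,
                                    timepoint = sub$timepoint,
                                    treatment = sub$treatment,
                                    value = sub[[metric]]),
                         metric = metric)
        d$nucleic_acid <- na
        rows[[paste(na, metric)]] <- d
      }
    }
    # paired beta distances within nucleic acid
    p <- samplePairs(dsAb)
    for (metric in names(betaBlock)) {
      for (na in c("DNA", "RNA")) {
        dmna <- if (na == "DNA") betaBlock[[metric]]$dmDNA
                else betaBlock[[metric]]$dmRNA
        pre <- stats::setNames(p$pair_id[p$timepoint == "pre"],
                               p$subject_id[p$timepoint == "pre"])
        post <- stats::setNames(p$pair_id[p$timepoint == "post"],
                                p$subject_id[p$timepoint == "post"])
        pb <- pairedBetaDistance(dmna, pre, post)
        pb$treatment <- p$treatment[match(pb$subject_id, p$subject_id)]
        rows[[paste(metric, na)]] <- data.frame(
          subject_id = pb$subject_id, treatment = pb$treatment,
          metric = paste0("paired_", metric), delta = pb$distance,
          nucleic_acid = na)
      }
    }
    out <- do.call(rbind, lapply(rows, function(r)
      r[, c("subject_id", "treatment", "nucleic_acid", "metric", "delta")]))
    rownames(out) <- NULL
    out
  })
  writeTSV(deltas, file.path(outdir, "deltas.tsv"))

  deltaTests <- withStage("delta_tests", {
    rows <- list()
    for (metric in unique(deltas$metric)) {
      sub <- deltas[deltas$metric == metric & !is.na(deltas$delta), ]
      if (length(unique(sub$treatment)) > 1L)
        rows[[paste(metric, "treatment")]] <-
          cbind(response = paste0("delta_", metric), predictor = "treatment",
                kruskalWallis(sub$delta, sub$treatment))
      if (length(unique(sub$nucleic_acid)) > 1L) {
        rows[[paste(metric, "nucleic")]] <-
          cbind(response = paste0("delta_", metric), predictor = "nucleic_acid",
                kruskalWallis(sub$delta, sub$nucleic_acid))
        rows[[paste(metric, "proxy")]] <-
          cbind(response = paste0("delta_", metric), predictor = "interaction",
                kruskalWallis(sub$delta,
                              interactionProxy(sub$nucleic_acid, sub$treatment)))
      }
    }
    if (!length(rows))
      return(data.frame(response = character(), predictor = character(),
                        method = character(), statistic = numeric(),
                        df = numeric(), p_raw = numeric(),
                        p_adjusted = numeric()))
    out <- do.call(rbind, rows)
    out$p_adjusted <- bhAdjust(out$p_raw)
    rownames(out) <- NULL
    out
  })
  writeTSV(deltaTests, file.path(outdir, "delta_tests.tsv"))

  # per-ASV relative-abundance changes, DNA vs RNA
  radTests <- withStage("relative_abundance_deltas", {
    dD <- relativeAbundanceDeltas(dsAb, "DNA")
    dR <- relativeAbundanceDeltas(dsAb, "RNA")
    p <- samplePairs(dsAb)
    arm <- p$treatment[match(rownames(dD), p$subject_id)]
    rows <- lapply(colnames(dD), function(a) {
      vals <- c(dD[, a], dR[, a])
      na <- rep(c("DNA", "RNA"), each = nrow(dD))
      tr <- rep(as.character(arm), 2L)
      kw <- kruskalWallis(vals, interactionProxy(na, tr))
      data.frame(asv_id = a, statistic = kw$statistic, df = kw$df,
                 p_raw = kw$p_raw)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- bhAdjust(out$p_raw)
    out
  })
  writeTSV(radTests, file.path(outdir, "relative_abundance_tests.tsv"))

  # --- RNA:DNA activity block ------------------------------------------
  dsAdj <- withStage("pseudocount", pseudocountAdjust(dsRar, cfg$pseudocount_mode))
  rm <- withStage("ratios", rnaDnaRatio(dsAdj))
  writeActivityTSV(rm, file.path(outdir, "rna_dna_ratios.tsv"))

  shiftBlock <- withStage("activity_shifts", {
    p <- samplePairs(dsAdj)
    out <- list()
    for (th in cfg$thresholds) {
      at <- classifyActivity(rm, th, strict = cfg$strict_threshold)
      pre <- new("ActivityTable",
                 states = at@states[p$timepoint == "pre", , drop = FALSE],
                 threshold = th, strict = cfg$strict_threshold,
                 pairs = p[p$timepoint == "pre", ])
      post <- new("ActivityTable",
                  states = at@states[p$timepoint == "post", , drop = FALSE],
                  threshold = th, strict = cfg$strict_threshold,
                  pairs = p[p$timepoint == "post", ])
      st <- shiftCode(pre, post, absentPolicy = cfg$absent_policy)
      key <- format(th)
      writeActivityTSV(at, file.path(outdir, paste0("activity_", key, ".tsv")))
      writeActivityTSV(st, file.path(outdir, paste0("shifts_", key, ".tsv")))
      out[[key]] <- list(activity = at, shifts = st,
                         dist = shiftDistance(st, cfg$shift_undefined))
    }
    out
  })

  shiftMantel <- withStage("shift_mantel", {
    keys <- names(shiftBlock)
    if (length(keys) < 2L) {
      data.frame(threshold_a = character(), threshold_b = character(),
                 r = numeric(), p_raw = numeric(), p_adjusted = numeric())
    } else {
    combs <- utils::combn(keys, 2L)
    mseeds <- withSeed(stageSeeds[3L], drawSeeds(ncol(combs)))
    rows <- lapply(seq_len(ncol(combs)), function(i) {
      a <- combs[1L, i]; b <- combs[2L, i]
      mt <- mantelTest(shiftBlock[[a]]$dist, shiftBlock[[b]]$dist,
                       cfg$permutations, seed = mseeds[i])
      data.frame(threshold_a = a, threshold_b = b,
                 r = mt$statistic, p_raw = mt$p_raw)
    })
    out <- do.call(rbind, rows)
    out$p_adjusted <- bhAdjust(out$p_raw)
    out
    }
  })
  writeTSV(shiftMantel, file.path(outdir, "shift_mantel.tsv"))

  # --- provenance -------------------------------------------------------
  stage("provenance")
  prov <- list(
    package = "pairedAmplicon",
    version = as.character(utils::packageVersion("pairedAmplicon")),
    config = cfg[setdiff(names(cfg), c("dna", "rna", "metadata"))],
    rarefaction_depth_used = rar$depth,
    stages = stages)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeFilterReports(reports, file.path(outdir, "filter_reports.json"))

  invisible(list(dataset_full = dsFull, dataset_abundant = dsAb,
                 dataset_rarefied = dsRar, dataset_adjusted = dsAdj,
                 proportion_living_full = plFull,
                 proportion_living_abundant = plAb,
                 alpha = alphaTab, alpha_tests = alphaTests,
                 beta = betaBlock, main_table = mainTable,
                 deltas = deltas, delta_tests = deltaTests,
                 ratio_matrix = rm, shifts = shiftBlock,
                 shift_mantel = shiftMantel,
                 rarefaction_depth = rar$depth))
}
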