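# pairedAmplicon

Paired DNA/RNA 16S amplicon analysis of the living and active members of
low-biomass bacterial communities.

## What problem this solves

16S rRNA *gene* amplicon sequencing counts DNA, so relic DNA from dead
cells and DNA from transient organisms inflate community profiles — a
serious distortion in low-biomass microbiomes such as the ocular
(conjunctival) surface. Sequencing the rRNA itself (reverse-transcribed to
cDNA) from the *same* swab restricts attention to taxa that are
transcribing ribosomes. Given one DNA-derived and one RNA-derived ASV
count table per swab event, this package:

* removes **phantom reads** (RNA reads for ASVs absent from the paired DNA
  sample) and screens for **abundant** ASVs (≥ 1% of any sample's reads);
* estimates the **proportion living** per swab — RNA richness over DNA
  richness, in (0, 1] after phantom removal;
* computes alpha diversity (richness, Shannon entropy, Pielou's evenness
  on rarefied counts) and beta diversity (Bray–Curtis on proportions,
  binary Jaccard), with PERMANOVA + beta-dispersion checks + pairwise
  post hocs, Mantel tests between the DNA and RNA distance matrices, and
  paired pre/post change statistics (Kruskal–Wallis, Benjamini–Hochberg);
* classifies per-ASV activity from **RNA:DNA ratios**
  r = RNA / (DNA + 1[RNA > 0]) at thresholds t ∈ {0.5, 1, 2}
  (active ⇔ r ≥ t), codes pre→post **activity shifts** as −1/0/+1, and
  compares shift structure across thresholds with Mantel tests on
  Euclidean shift-distance matrices;
* generates **synthetic paired studies** with known living / dormant /
  relic / transient structure and a bacteriostatic (or bactericidal)
  treatment effect, so every stage is validated against ground truth.

It is written for microbial ecologists analysing paired rDNA/rRNA designs
with small, longitudinal cohorts. Inputs are plain TSV or BIOM-JSON
feature tables plus a five-column sample metadata sheet; all outputs are
tidy TSV plus a JSON provenance log.

## Worked example

Simulate the default study (7 subjects — 3 control, 4 antibiotic — swabbed
pre and post, 800 ASVs, read depths in the tens of thousands) and run the
full analysis:

```r
library(pairedAmplicon)

study <- generateStudy(scenarioConfig(seed = 42))
study$dataset
#> PairedAmpliconSet: 14 sample pairs, 800 ASVs
#>   timepoints: pre=7, post=7
#>   subjects: 7

res <- runAnalysis(pipelineConfig(dnaCounts(study$dataset),
                                  rnaCounts(study$dataset),
                                  study$metadata, seed = 7),
                   "results/demo")

head(res$proportion_living_full[, c("pair_id", "dna_richness",
                                    "rna_richness", "proportion_living")], 4)
#>   pair_id dna_richness rna_richness proportion_living
#> 1  S1_pre          704          249         0.3536932
#> 2 S1_post          654          222         0.3394495
#> 3  S2_pre          695          243         0.3496403
#> 4 S2_post          687          230         0.3347889
```

About a third of the DNA-detected ASVs are living here, consistent with
the generator's default 55% dead-only + 8% transient pool (rare living
taxa missed in one of the two tables account for the rest). The summary
table mirrors the usual diversity-analysis layout — test statistic, R²
where applicable, BH-adjusted p:

```r
subset(res$main_table, response == "bray_curtis")
#>       response         predictor statistic  r_squared p_adjusted
#> 14 bray_curtis      nucleic_acid 1.9154033 0.07330429      0.045
#> 15 bray_curtis         treatment 0.8408320 0.06435887      1.000
#> 16 bray_curtis       interaction 0.2662091 0.02037615      1.000
#> 17 bray_curtis mantel_dna_vs_rna 0.9832289         NA      0.001
```

DNA and RNA profiles differ (nucleic acid term) yet track each other
closely (Mantel r = 0.98): dead taxa shift the composition without
decoupling the two views of community structure. Shift-matrix agreement
across RNA:DNA thresholds:

```r
res$shift_mantel
#>   threshold_a threshold_b         r p_raw p_adjusted
#> 1         0.5           1 0.7545405 0.001     0.0030
#> 2         0.5           2 0.3261606 0.173     0.1730
#> 3           1           2 0.5217946 0.027     0.0405
```

The two lower cut-offs agree with each other far more than either agrees
with the stringent cut-off of 2 — the ratio distribution sits mostly below
2, so that threshold sees different shifts.

A thin command-line wrapper over the same functions lives at
`inst/scripts/paired-amplicon.R` (subcommands `simulate`, `analyze`,
`compare-thresholds`).

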