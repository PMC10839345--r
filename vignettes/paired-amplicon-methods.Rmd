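---
title: "Methods: paired DNA/RNA amplicon analysis of living and active bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired DNA/RNA amplicon analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedAmplicon)
```

## The problem

16S rRNA gene amplicon sequencing counts DNA molecules, not living cells.
Relic DNA from dead cells and DNA from transient, non-resident organisms
inflate DNA-based richness, and in low-biomass communities — conjunctival
surfaces being an extreme case — the dead and transient fraction can
dominate. Sequencing the rRNA itself (as cDNA) from the same swab
restricts attention to taxa that are transcribing ribosomes, i.e. the
living and active community. `pairedAmplicon` implements the analysis of
such paired designs: one DNA-derived and one RNA-derived ASV count table
per swab event, collected from the same subjects before and after a
perturbation (here, a bacteriostatic antibiotic that suppresses activity
without killing).

The package takes denoised ASV tables as input. Demultiplexing, denoising,
chimera removal and taxonomy assignment are upstream concerns; taxonomy is
carried only as optional labels.

## Filtering model

Four post-denoising steps, in the fixed order the pipeline applies them:

1. **Phantom-read removal.** An RNA read for an ASV absent from its paired
   DNA sample contradicts the model that the RNA community is a subset of
   the DNA-detected community; such reads are treated as artifact and
   zeroed, per pair. A `global` mode (zero RNA only for ASVs with no DNA
   reads anywhere) is available for sensitivity analysis. After this step
   RNA support ⊆ DNA support in every pair, so the per-pair *proportion
   living* — RNA richness / DNA richness — lies in (0, 1].
2. **Abundance screen.** An ASV is *abundant* if it reaches at least 1%
   (configurable) of the reads of at least one sample, DNA or RNA; the
   comparison is `>=`, so an ASV exactly at the threshold is kept. The
   screen is idempotent: dropping columns only raises the survivors'
   proportions. Whether to screen before or after phantom removal is not
   dictated by the data; the pipeline screens after, matching the order in
   which the filters are motivated (phantom reads are artifacts; the
   screen is a scope decision).
3. **Rarefaction.** For analyses that compare richness-like quantities,
   each sample is subsampled without replacement to the lowest read depth
   in the abundant dataset (or an explicit depth). The subsample is drawn
   by `vegan::rrarefy` under a caller-supplied seed; row sums equal the
   depth exactly and reruns are bit-identical.
4. **Pseudocount.** Rarefaction can zero a DNA count whose paired RNA
   count stayed positive, making an RNA:DNA ratio undefined. Wherever RNA
   is positive, 1 is added to the paired DNA count. Read literally, the
   increment applies to *every* RNA-positive cell, not only those where
   rarefaction zeroed the DNA; both readings are defensible, so both are
   implemented (`mode = "all"`, the default, and `mode = "zeros"`). The
   default adds exactly (number of RNA-positive cells) reads to the DNA
   table, a bias of at most 1 read per cell that is immaterial at
   rarefaction depths in the tens of thousands.

## Diversity and paired-change statistics

Alpha diversity (richness, Shannon entropy in bits, Pielou's evenness) is
computed on the rarefied abundant table; evenness is entropy over
log2(richness) and is undefined at richness ≤ 1. Entropy base 2 is a
convention only — evenness is base-invariant and the base is configurable.

Beta diversity uses Bray–Curtis on per-sample *proportions* (sequencing
effort is arbitrary, so only composition is meaningful) and binary Jaccard
on supports. Group structure is tested with PERMANOVA (`vegan::adonis2`,
sequential sums of squares in the order nucleic acid, treatment state,
interaction), validated against a beta-dispersion permutation test so a
location effect is not confused with a spread effect, with pairwise post
hoc PERMANOVAs BH-adjusted. Agreement between the DNA and RNA views of
community structure is measured by a Mantel test between the two distance
matrices over swab events.

Longitudinal change is strictly paired: post minus pre within subject, for
proportion living, each alpha metric within nucleic acid, the pre/post
beta distance, and per-ASV relative abundance (whose within-subject deltas
sum to zero by construction — a compositional constraint worth remembering
when interpreting per-taxon changes). Because group sizes are small, group
comparisons of these scalars use Kruskal–Wallis tests with
Benjamini–Hochberg adjustment; the "interaction" of nucleic acid and
treatment is a concatenated proxy factor (e.g. `RNA.antibiotic`), a single
rank test on the crossed labels rather than a modeled interaction term.
With every observation tied, Kruskal–Wallis is reported as H = 0, p = 1
rather than the NaN the χ² machinery produces.

## RNA:DNA activity ratios

For each pair and abundant ASV, the activity ratio is the RNA count over
the pseudocount-adjusted DNA count. Cells with neither RNA nor DNA reads
carry no information and are *absent* — flagged, never coerced to zero.
An ASV is *active* at threshold t if its ratio is ≥ t, with the
conventional thresholds 0.5, 1 and 2 spanning assumptions from
"half the population active / extra gene copies / relic DNA" to "more
rRNA than gene copies per cell". The boundary uses `>=`; a strict `>`
mode exists and differs only at cells exactly on the threshold, which
integer ratios from rarefied counts do hit. Active sets nest as the
threshold grows, a monotonicity the tests enforce on random inputs.

Pre-to-post shifts are coded −1 (to inactive), +1 (to active), 0 (no
shift). A transition involving an absent state is *undefined* by default
and excluded, because taxa absent at one timepoint can masquerade as
activity shifts; an absent-as-inactive mode replicates pipelines that do
not make this distinction. Subjects' shift vectors are compared across
thresholds by Mantel tests on Euclidean shift-distance matrices, with
undefined codes imputed as 0 (and the imputation count logged) or the
affected ASVs dropped, by choice.

## The synthetic-data generator

Ground truth is unobtainable for real swabs, so every stage is validated
against a generative model with known structure. Each ASV carries: a
latent living abundance (lognormal, meanlog 0, sdlog 2 — heavy-tailed, as
species-abundance distributions are), a relic abundance for dead-only
taxa, an activity level (bimodal: active 0.8, dormant 0.05), an rRNA
factor and gene-copy number (both 1 by default so ratios are directly
interpretable; lognormal heterogeneity switches model the copy-number
caveat), a susceptibility flag, and a transient flag for DNA-only
contaminants whose mass is redrawn each timepoint. DNA read probabilities
are proportional to (living + relic) × gene copies; RNA probabilities to
living × activity × rRNA factor; reads are multinomial at the configured
depths. Multinomial (rather than Dirichlet-multinomial) sampling keeps
expectations exactly computable for the recovery tests.

Defaults mirror a small ocular perturbation study: 7 subjects (3 control,
4 antibiotic), 2 timepoints, 800 ASVs of which 55% are dead-only and 8%
transient, DNA depths 19,821–58,962 and RNA depths 28,721–83,021 per
sample, and a bacteriostatic treatment multiplying susceptible taxa's
activity by 0.1. A between-timepoint lognormal drift (sdlog 0.5) on every
living abundance emulates the strong temporal turnover such data show in
both arms; setting it to 0 isolates treatment effects. A bactericidal
mode reduces living abundance instead of activity.

Two consequences of the model are worth stating because they are the
mechanisms the package's validation leans on:

* **Compositional blindness.** If every taxon is susceptible and rRNA
  factors are equal, a bacteriostatic hit multiplies all RNA
  probabilities by a common factor, which cancels in the multinomial —
  expected RNA proportions are *exactly* unchanged. Amplicon data cannot
  see a uniform activity reduction. The acceptance suite verifies both
  the exact invariance and its converse (a patchy bactericidal hit is
  detectable). Because a matched-seed rerun of the uniform-hit arm
  produces bit-identical counts (the factor cancels before sampling), the
  two arms of that comparison use matched configurations and depths but
  disjoint replicate seed streams.
* **Detection-limit bias.** Proportion living is a richness ratio, and
  richness saturates with depth. Rare living taxa must be detected in
  *both* tables to count; under the default heavy tail this depresses the
  estimate by a few percentage points at depth 20,000 — the recovery
  test's ±0.05 band absorbs it, and deeper sequencing shrinks it.

## Numerical and design choices

* **Seeds.** Every random stage (rarefaction, permutations, simulation)
  takes an explicit seed; sub-stages derive independent seeds from it, so
  a pipeline run is reproducible end to end and intermediate stages can
  be rerun in isolation. The caller's RNG state is never disturbed.
* **NMDS.** Ordination is plotting-only. The default run starts from the
  deterministic principal-coordinate embedding refined by Kruskal's
  stress-1 NMDS (`vegan::monoMDS`), which makes it reproducible without
  an RNG and equivariant under relabelling; optional random restarts
  (`tries`) can escape local minima when a plot looks suspect. This was
  chosen over always-random multi-starts precisely for those two
  properties.
* **Permutations.** 999 by default; PERMANOVA p-values are
  (1 + exceedances)/(1 + permutations). At very small n the machinery
  switches to complete enumeration, which is exact and silently accepted.
* **Degenerate inputs.** All-zero samples are errors in diversity
  calculations; zero-total samples contribute no qualifying ASVs to the
  abundance screen (warning); zero DNA richness makes proportion living
  missing (warning); fewer than 3 subjects make shift distances, and
  fewer than 4 objects make Mantel/NMDS, errors.
* **Eye pooling.** Both eyes' swabs are pooled into one tube upstream;
  the package models one sample per swab event and no eye-level
  structure.

## What the tests do and do not show

The test suite validates the arithmetic and the statistical machinery
against independent oracles (brute-force step-up FDR, full-enumeration
PERMANOVA and Mantel p-values, hypergeometric rarefaction expectations),
and validates the pipeline's inferences against generator ground truth at
study scale: filter contracts on 1,000 random paired tables, threshold
nesting, null calibration of the rank and permutation tests, recovery of
the living fraction (±0.05 at depth 20,000 with 1,000 ASVs over 7
subjects) and of activity states (≥0.9 accuracy at threshold 0.5 when
active and dormant expected ratios straddle it: activity × rRNA of 2
vs 0.1, on ASVs with expected DNA count ≥ 20), and byte-level determinism
of two identically seeded runs. Synthetic data are multinomial with
shared per-taxon biology across subjects; real data add overdispersion,
copy-number heterogeneity, contamination structure and eye-level effects
the defaults do not model, so passing tests certify the method's
internal correctness, not its field error rates.

## Limitations

RNA:DNA ratios inherit all the caveats of their inputs: rRNA content per
cell varies across taxa and physiological states, dormant cells can hold
ribosomes, and gene-copy number varies severalfold; the generator's
heterogeneity switches exist to explore, not to correct, these effects.
No per-taxon copy-number correction is attempted. Phylogenetic diversity
metrics are out of scope. Differential-abundance machinery beyond paired
proportion deltas with rank tests is deliberately absent — at 7 subjects,
model-based methods promise more than the design can deliver.
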