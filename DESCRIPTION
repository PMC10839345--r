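Package: pairedAmplicon
Title: Paired DNA/RNA 16S Amplicon Analysis of Living and Active Bacterial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing paired 16S rDNA and rRNA (cDNA) amplicon
    count tables from the same biological samples, aimed at low-biomass
    host-associated microbiomes where relic DNA from dead cells inflates
    DNA-based community profiles. Implements phantom-read removal,
    abundance screening, seeded rarefaction and the pseudocount adjustment
    needed for RNA:DNA ratios; per-sample proportion-living estimates;
    alpha and beta diversity with paired pre/post change statistics;
    RNA:DNA activity classification at configurable thresholds with
    activity-shift coding and shift distance matrices; a permutation
    statistics layer (Kruskal-Wallis, Benjamini-Hochberg, PERMANOVA,
    beta dispersion, Mantel); and a synthetic paired-community generator
    with known living, dormant, relic and transient structure for
    validating every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    BiocGenerics,
    vegan,
    biomformat,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'tablesIO.R'
    'filtering.R'
    'diversity.R'
    'longitudinal.R'
    'activity.R'
    'statsTests.R'
    'synthetic.R'
    'pipeline.R'
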