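Package: saltQTL
Title: Bin-Map QTL Mapping and Salt-Specific Expression Analysis for Rice RIL Populations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrated linkage-mapping and comparative-transcriptome pipeline for
    nominating salt-tolerance candidate genes in a bi-parental rice recombinant inbred
    line (RIL) population. Builds recombination bin maps from noisy resequencing
    genotypes with a sliding-window caller and the Kosambi map function, fits the
    multi-environment random-effects model for line BLUPs and broad-sense heritability,
    scans bin markers for QTL with permutation-derived genome-wide thresholds, 2-LOD
    support intervals and a cross-condition stability rule, classifies salt-specific
    differentially expressed genes into six condition-specific classes, and colocalizes
    shared DEGs with stable QTL intervals. Ships a seeded synthetic-data generator that
    emulates the study design (single-seed-descent RILs, balanced multi-environment
    phenotypes, an eight-library bulked-segregant expression design) with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, QTLMapping, GeneExpression, DifferentialExpression, Software
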