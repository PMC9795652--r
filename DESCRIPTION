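Package: microtype
Title: Microbiome Steady-State Typing and Multi-Omics Integration for Host Phenotype Cohorts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream multi-omics analysis of stool microbiome cohorts:
    community "steady-state" typing by Ward clustering of sample-wise Spearman
    correlations with Benjamini-Hochberg within-cluster validation and
    permutational MANOVA; genus co-abundance group (CAG) inference from
    FDR-gated positive Kendall correlations with Wiggum-plot statistics;
    UniFrac/PCoA ordination with permutation-tested metadata and food-frequency
    vector fits; dietary patterning by correspondence analysis and the Healthy
    Food Diversity index; RNA:DNA-normalized transcriptional activity measures
    with an "active species" rule and KO-panel ratios; sparse partial least
    squares coupling of metatranscriptome and lipidome blocks; and median
    (quantile) age-adjusted regression of host behavioral scores on ordination
    axes. A seeded synthetic-cohort generator plants the statistical structure
    each stage assumes (community clusters, co-abundance blocks, dietary
    archetypes, lipid panels, expression multipliers) so the whole pipeline is
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    vegan,
    phyloseq,
    cluster,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    optparse
Config/testthat/edition: 3
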