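Package: temposcan
Title: Temporal Genome Scans for Selection in Predominantly Selfing
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects selection footprints between two temporal samples of
    the same (predominantly selfing) population, as in resurrection-style
    studies of crop landraces. Implements two complementary FST-outlier
    genome scans: a drift-simulation null tailored to partially selfing
    populations (genotype-frequency based, with effective population size
    estimated from the temporal FST) and an FDist-style test comparing
    observed locus (heterozygosity, FST) pairs against a structured
    coalescent null simulated under a hierarchical island model. Also
    provides the surrounding population-genetic statistics (locus
    filtering, Weir-Cockerham F-statistics, LD decay profiles),
    aggregation of significant SNPs into independent loci under selection,
    annotation-overlap and fold-enrichment statistics, standardized
    climate-anomaly (Lamb index) analysis, phenology contrasts, and a
    forward individual-based simulator of partially selfing populations
    used as the synthetic data source for the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
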