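Package: coremicro
Title: Core Microbiome Extraction and Culture-Collection Coverage of
    Metagenomic Profiles
Version: 0.1.0
Authors@R: person("coremicro", "developers", role = c("aut", "cre"),
    email = "coremicro@example.org")
Description: Tools for cohort-level gut microbiome profiling: normalization
    of compositional relative-abundance tables, per-taxon summary statistics
    (mean relative abundance, prevalence, abundance strata), dual-threshold
    extraction of dominant, common and core taxa, assessment of how
    completely a cultured strain biobank covers a metagenomic taxon profile
    (stratified count coverage, abundance-mass coverage, cultured-but-
    undetected complement, cross-biobank unique species), rank-based
    association of taxon abundances with clinical indices (Spearman
    correlation, Wilcoxon rank-sum cohort comparison, significance-star
    annotation), and a seeded zero-inflated log-normal cohort simulator
    with planted core taxa, cohort-differential taxa and monotone clinical
    correlations for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
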