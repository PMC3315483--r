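Package: mqtlnet
Title: Metabolite QTL Mapping and Correlation-Network Analysis for
    Introgression-Line Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for GC-MS metabolite profiles measured on
    introgression-line (IL) populations against a recurrent-parent control.
    Provides sample-median and reference-sample normalization, one-way ANOVA
    screening followed by Dunnett many-to-one testing with Bonferroni
    correction to call metabolite QTL, cross-season confirmation by two-way
    ANOVA and localization of calls onto overlapping introgressed segments,
    coefficient-of-variation plasticity profiles and broad-sense heritability
    from expected mean squares, thresholded Pearson correlation networks with
    topology measures, a variance-matched permutation framework for comparing
    network topology between tissues, modularity significance tests, and
    trait-metabolite association matrices.  A synthetic-population generator
    with block-structured covariance and planted genotype effects supports
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    mvtnorm,
    car,
    stats,
    utils
Suggests:
    multcomp,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
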