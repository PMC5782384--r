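Package: ailqtl
Title: Genetical Genomics for Advanced Intercross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linkage mapping of quantitative traits and liver gene expression
    in advanced intercross lines (AILs) between divergent founder populations,
    modelled on a wild x domestic chicken F8 intercross. Provides multipoint
    genotype probabilities via a hidden Markov model, Haley-Knott regression
    genome scans with covariates and genotype-by-sex interactions, permutation
    significance thresholds, 1.8-LOD support intervals, two-dimensional
    epistasis scans, multiple-QTL models, expression QTL mapping with
    local/distal classification and subsampled-probeset permutation
    thresholds, trans-regulatory hotspot detection against a random-placement
    null with conditional mediation analysis, candidate-gene integration of
    QTL and local eQTL, and selective-sweep overlap testing. Includes a
    configurable simulator of F8 advanced intercrosses with planted trait QTL
    and expression-QTL architectures so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    sva,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
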