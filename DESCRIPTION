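Package: gynodet
Title: Cyto-Nuclear Sex Determination Analysis for Gynodioecious Strawberry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a three-locus epistatic model of cyto-nuclear sex
    determination in gynodioecious wild strawberry (Fragaria vesca subsp.
    bracteata): exact Mendelian progeny sex-ratio prediction with optional
    viability selection, seeded simulation of crossing designs and linked
    marker data, goodness-of-fit and marker-trait association statistics,
    joint maximum-likelihood inference of parental genotypes from a crossing
    design, single-family two-point LOD mapping of male sterility with
    perfect-cosegregation interval calling, and windowed gene-class density
    scans over genome annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
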