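Package: lactQTL
Title: Wood Lactation Curves and Single-Family QTL Mapping for Milk
    Persistency Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits Wood lactation curves to longitudinal milk records,
    derives lactation-persistency and extended-lactation traits (milk,
    protein, fat, lactose, useful yield, somatic cell score), and maps
    quantitative trait loci in a single-sire backcross/half-sib family by
    two routes: a finite-mixture maximum-likelihood interval scan with LOD
    classification and 1-LOD support intervals, and half-sib regression
    with permutation significance thresholds, bootstrap position
    confidence intervals, a two-QTL grid search and QTL heritability.
    Includes a synthetic-study generator emulating a dairy-sheep backcross
    design (172 daughters, 189 microsatellites on 26 autosomes) so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'wood-fit.R'
    'derived-traits.R'
    'linkage.R'
    'scan-mle.R'
    'scan-regression.R'
    'simulate.R'
    'pipeline.R'
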