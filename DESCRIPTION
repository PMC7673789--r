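Package: psiscale
Title: Scaling of Mutational Effects on Exon Inclusion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the scaling law relating inclusion-independent
    splicing-efficiency effects (A) of mutations to their observed changes
    in exon inclusion (delta PSI) at any starting inclusion level, together
    with the analyses built on it: scoring of deep mutational scanning
    (DMS) variant counts into enrichment scores and PSI estimates with a
    bounded Bayesian correction and mode adjustment, rescaling of mutation
    effect distributions with bootstrap confidence bands, genome-wide
    prediction of delta-PSI distributions from an exon-by-tissue PSI atlas,
    allele-dosage effect estimation by linear regression with per-event
    pruning and exon-class comparison, and hexamer splicing-enhancer
    robustness analytics. A synthetic-data generator produces every input
    the pipeline consumes so all stages are testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
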