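Package: planktotyper
Title: Genotyping and Delimitation of Pseudo-Cryptic Planktonic Foraminifera
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage pipeline for splitting a planktonic foraminiferal
    morpho-species into pseudo-cryptic genetic species. Provides in-silico
    restriction-fragment (RFLP) genotyping of rDNA amplicons, alignment
    consensus masking with synapomorphy diagnosis, patristic-distance
    summaries and a barcode-gap delimitation test, rare-genotype
    detection-probability calculus, water-column thermal-niche
    characterization of core-top assemblages (inverse-angular-distance
    interpolation and correlation-matrix PCA of depth temperatures), and
    two-group morphometric discrimination with Wilks' lambda and
    nonparametric distribution tests. A synthetic-data module generates
    every input with the statistical structure the analysis assumes, so
    the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    MASS,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
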