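Package: bescreen
Title: Efficiency-Corrected Analysis of Base-Editing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled CRISPR base-editing screens with editing
    efficiency correction. Designs CBE/ABE guide libraries over supplied
    reference sequences, maps per-guide editing outcomes and efficiencies from
    paired guide-target assay reads with background-error correction, computes
    negative-control-anchored ln fold changes, scores variants with
    efficiency-corrected beta scores (beta = d/q), and classifies
    loss-of-function variants with a four-component Gaussian mixture model.
    Includes a simulator that generates screens and target-site assay reads
    under an exponential growth model with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
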