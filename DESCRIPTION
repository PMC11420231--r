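Package: paleosex
Title: Multi-Proxy Biological Sex Determination for Archaeological Assemblages
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating biological sex in commingled archaeological
    skeletal assemblages from three complementary lines of evidence:
    sex-specific amelogenin peptide peak areas measured in tooth enamel by
    targeted mass spectrometry, X/Y read-count ratios (RY and RX) from
    low-coverage shotgun sequencing of ancient DNA, and osteological sex
    calls consumed as given. Includes stratified sex-ratio analysis of a
    cemetery population with probable-inclusion policies and natural/extreme
    range classification, plus calibrated simulators for per-chromosome read
    counts, peptide peak areas and whole-cemetery individual tables so every
    stage of the pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
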