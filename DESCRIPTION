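Package: admixchron
Title: Ancestry Statistics and Calendar Dating of Admixture Events from
    Ancient DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the ancestry and chronology of admixed
    ancient populations from pseudo-haploid genotype data: f4-statistics with
    weighted block-jackknife standard errors, inverse-variance-weighted
    f4-regression, qpAdm-style constrained mixture fitting with autosome
    versus X-chromosome sex-bias tests, admixture-LD decay dating of
    admixture events in generations, radiocarbon calibration against mixed
    terrestrial and marine curves with reservoir corrections, and propagation
    of genetic, generation-interval and radiocarbon uncertainties into
    calendar admixture dates with sensitivity grids. Includes a synthetic
    cohort generator with known admixture proportions, admixture times and
    sex bias so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
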