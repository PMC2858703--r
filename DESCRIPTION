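Package: clscreen
Title: Pooled Barcode Screen Analysis for Yeast Chronological Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled yeast knockout-collection chronological
    lifespan screens read out on two-channel TAG (molecular barcode) microarrays.
    Computes per-mutant abundance ratios from UPTAG/DNTAG channel intensities,
    estimates nonspecific-hybridization background from essential-gene probes,
    filters the analysable gene universe, and calls short-lived, long-lived and
    calorie-restriction-unresponsive candidate mutants by rank and ratio
    thresholds with spreadsheet-compatible competition ranking. Includes a
    synthetic pooled-screen simulator (Weibull viability decay, multinomial
    plating recovery, tag-specific hybridization efficiency, log-normal intensity
    noise, adaptive regrowth), colony-forming-unit lifespan assay summaries, and
    reproducible file-based pipeline stages with run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
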