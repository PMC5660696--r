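Package: matsip
Title: Single-Cell Stable Isotope Probing of Phototrophic Microbial Mats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying single-cell carbon and nitrogen assimilation
    in microbial mats from combined NanoSIMS imaging and compound-specific
    isotope analysis (CSIA) of fatty acid methyl esters (FAME). Provides
    isotope-notation conversions (ratio, atom percent, delta) and two-pool
    label mixing mass balance; correction of measured FAME delta-13C to
    free-fatty-acid values; loading, plane accumulation, coccoid-cell
    segmentation and per-ROI isotope-ratio measurement of multi-channel
    secondary-ion count stacks; enrichment-fraction and per-cell substrate
    flux calculations with community-scale extrapolation; the Van der Waerden
    normal-scores test with compact letter display, ANCOVA slope-homogeneity
    tests; and a ground-truthed synthetic-data generator (Poisson ion-counting
    forward model, labelled FAME tables) for validating the whole chain.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
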