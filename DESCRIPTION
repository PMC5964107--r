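Package: aeroflux
Title: Taxon-Specific Aerosolization Analysis for Ocean-Atmosphere Mesocosms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying taxon-specific transfer of bacteria and
    viruses across the air-sea interface in mesocosm experiments. Computes
    aerosolization factors (the ratio of a taxon's relative abundance in sea
    spray aerosol to its abundance in bulk seawater or the sea surface
    microlayer) and surface-enrichment factors from taxon-by-sample abundance
    tables, applies abundance-threshold and genome spatial-coverage filters,
    classifies taxa as constitutive or intermittent aerosolizers, analyses
    compartment particle-count ratios with uncertainty propagation, and
    simulates synthetic mesocosm communities with known ground truth for
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
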