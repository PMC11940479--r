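Package: mrtfrac
Title: Combined Temporal and Spatial Dose Fractionation Analysis for
    Microbeam Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models multi-fraction microbeam (MRT) and broad-beam absorbed-dose
    fields with per-fraction in-plane rotation, computes spatially integrated
    linear-quadratic (LQ) cell survival and the equivalent uniform single-fraction
    dose (EUD), reduces clonogenic colony-formation-assay data to survival
    fractions and fits LQ parameters, and compares treatment modalities with
    ANCOVA on survival curves. A synthetic colony-formation-assay generator
    reproduces the study design (three modalities, four daily fractions,
    replicated Poisson colony counts) so every stage of the pipeline is testable
    end to end.
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
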