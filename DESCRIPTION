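Package: granupbm
Title: Bi-Component Population Balance Modelling of High-Shear Wet Granulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates bi-component high-shear wet granulation with a
    three-coordinate population balance (drug substance volume, excipient
    volume, pore volume) and lumped internal/external binder liquid.
    Formulation-dependent nucleation partitions spray drops between immersion
    nuclei and solid-spread "liquid marble" nuclei; granules then evolve by
    rewetting, excipient layering, marble-driven surface growth, aggregation
    with a capillary/viscous collision-efficiency kernel, consolidation and
    optional breakage on a geometric volume grid with moment-conserving
    cell-average redistribution and CFL-bounded explicit Euler stepping.
    Includes size-distribution and content-uniformity (demixing potential)
    analysis, perturbation sensitivity scans, synthetic experiment fixtures
    and two-objective Pareto parameter estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
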