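Package: stratodyn
Title: Fossil Diversity Dynamics and the Sedimentary Rock Record Under
    Age Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying Ediacaran-Cambrian (~580-510 Ma)
    macroevolutionary dynamics jointly with the sedimentary rock record.
    Implements Monte Carlo resampling of genus-level fossil ranges under a
    four-category age-uncertainty scheme, moving-window genus richness and
    Foote per-capita origination/extinction rates from boundary-crosser
    counts, lithostratigraphic volume- and area-flux budgeting on a 50-ka
    grid, fossiliferous-surface sampling-intensity series, genus-density
    normalization, and a Spearman rank correlation suite (raw and
    first-differenced, with moving-window smoothing) linking biodiversity,
    rock quantity, sampling, and carbonate carbon / uranium isotope series.
    Includes a synthetic-data generator that emulates the statistical
    structure of such compilations and records the generating truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
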