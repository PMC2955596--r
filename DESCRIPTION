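Package: mobscore
Title: Composite Mobility Profiling for Lower-Limb Amputee Assessment Batteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores multidimensional mobility assessment batteries for older
    adults with lower-limb amputations of vascular origin. Raw scores from 16
    clinical instruments are dichotomized against published fail thresholds,
    aggregated into missing-data-weighted composite scores (0-4) for three
    dimensions (mobility modulators, potential mobility, effective mobility),
    categorized as low/moderate/high, and combined into four mobility profile
    groups (A-D). Includes a configurable synthetic-cohort generator for
    heterogeneous amputee populations (prosthesis walkers, walking-aid users,
    wheelchair users), a deterministic ten-participant pilot fixture, CSV/YAML
    input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
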