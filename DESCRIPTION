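Package: xrefine
Title: Decision Algorithms for Crystallographic Model Re-Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the decision-making layer of an automated
    crystallographic re-refinement and rebuilding pipeline: reflection-data
    sanitation, R-free test-set validation, creation and bias detection,
    resolution/data-density model categories, B-factor parameterization
    selection via Hamilton R-factor ratio tests, overfitting-guarded
    selection of the best model from candidate refinements, real-space
    density-fit scoring with water pruning, and a deterministic pipeline
    state machine driven by an abstract refinement-engine interface so
    every decision path can be exercised without an external refinement
    program. Includes synthetic generators for reflection data, density
    maps and engine responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    bio3d,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
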