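Package: hipmorph
Title: Three-Dimensional Hip Morphometry Across Pelvic Tilt
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies acetabular coverage of the femoral head in 3D hip
    models as a function of anterior pelvic plane (APP) tilt. Builds the
    APP-anchored pelvic coordinate frame from landmarks, fits the femoral-head
    sphere, and computes the lateral center-edge angle (LCEA), the anterior
    center-edge angle (ACEA, 65-degree false-profile construction), and the
    horizontal-plane acetabular coverage fraction over a -30 to +30 degree
    tilt sweep. Includes a parametric synthetic-hip generator with closed-form
    ground truth for validation, cohort-level statistics (sex comparisons,
    coverage correlations, intraclass-correlation reliability), and a packaged
    published-cohort summary table for range/peak arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
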