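Package: ovogeom
Title: Egg-Shaped Fruit Geometry from Two-Dimensional Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the explicit Preston equation to digitized two-dimensional
    fruit profiles and, under the solid-of-revolution assumption, computes
    fruit volume and surface area from the fitted parameters. Includes a
    digitization pipeline for binary silhouette images (boundary tracing,
    caliper-based scale calibration, arc-length resampling), Nelder-Mead
    parameter estimation scored by the width-adjusted root-mean-square error,
    allometric log-log scaling analyses with slope confidence intervals, a
    predicted-versus-observed volume test of the solid-of-revolution
    assumption, Tukey HSD group comparisons, and a synthetic-cohort generator
    emulating egg-shaped tomato cultivars for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
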