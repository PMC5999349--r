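Package: rtdcstats
Title: Statistical Analysis of Real-Time Deformability Cytometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A statistical toolbox for real-time deformability cytometry
    (RT-DC) experiments. Computes per-cell morphological and texture
    features from pixel contours and bright-field image patches (area,
    volume of revolution, circularity and deformation, second-moment
    inertia ratio and orientation, convexity gate, symmetry ratios,
    brightness and the 13 Haralick features), screens feature
    distributions for normal versus log-normal behaviour with Filliben
    probability-plot correlation, detects sub-populations with
    full-covariance Gaussian mixture models selected by the Bayesian
    information criterion together with a density-contour overlap and
    assignment-accuracy assay, projects multi-feature tables onto
    principal components to screen for rare sub-populations, forms the
    bootstrap differential-deformation statistic between reservoir and
    channel regions, and tests treatment effects across biological
    replicates with a random-intercept/random-slope linear mixed model
    and a likelihood-ratio test. A synthetic-data module generates
    parametric contours, artificial area/modulus populations mapped to
    deformation through a documented surrogate mechanical model, and
    replicate-structured two-condition datasets, so every method can be
    exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
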