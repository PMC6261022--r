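Package: ostfmri
Title: Individualized Optimal Stopping Times for Task fMRI via Volume-Wise GLM Convergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how long a task-fMRI acquisition needs to run for each
    subject by tracking volume-by-volume general linear model (GLM) beta-weight
    trajectories, modelling their change (the sum of absolute differences,
    SoAD) as exponential decay, and converting the decay constant into
    half-life based optimal stopping times (OSTs). Ships a complete synthetic
    stop-signal-task study: an adaptive stop-signal-delay staircase with a
    horse-race behavioral simulator, a generator of independent-component
    timecourses whose trial-by-trial amplitude variance controls convergence
    speed, the incremental volume-wise GLM engine, robust log-linear decay
    fitting, and validation of OST-truncated neural features against full-task
    features via balanced leave-one-out linear SVM classification with
    Wilcoxon rank tests and behavioral reaction-time correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
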