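Package: rpmdetect
Title: Unsupervised Online Change Detection in EEG-Like Signal Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time, unsupervised change-point detection for single-channel
    EEG-like data streams. Sliding-window time-domain features (mean, extrema,
    variance, standard deviation) are combined into a joint entropy value per
    sample; residuals from a degenerate (zero-trend) autoregressive mean model
    are standardized online and converted to strangeness scores; a Randomized
    Power Martingale over conformal randomized p-values declares a change when
    it exceeds an adjustable threshold, giving a Doob-bounded false-alarm rate.
    Includes stream readers for plain-text/CSV signal files, decimation,
    precision/recall/F-score evaluation against ground-truth change lists,
    threshold sweeps, and a synthetic stream generator with known change points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
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
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    patchwork,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
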