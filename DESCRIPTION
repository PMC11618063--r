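Package: replimix
Title: Replication Probabilities for Meta-Analytic Effect Sizes via
    Gaussian Scale-Mixture Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the probability that an exact replication of a study
    reaches statistical significance in the same direction as the original,
    from large collections of meta-analytic effect sizes. Fits a weighted
    zero-mean Gaussian scale mixture to z statistics, deconvolves it to the
    distribution of the signal-to-noise ratio (SNR), and derives replication
    probabilities, statistical power distributions and sample-size
    requirements for replication studies. Simultaneous 95% confidence bands
    are obtained by a Dvoretzky-Kiefer-Wolfowitz F-localization over a dense
    scale-mixture class with a censored folded-normal model, solved as
    linear-fractional programs. Includes a synthetic meta-analytic cohort
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
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
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
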