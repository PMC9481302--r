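Package: gddrn
Title: Growth Degree-Day Reaction-Norm Models for Multi-Trait Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Environmental characterization of multi-environment field trials at
    100 growing-degree-day stages, bespoke covariance kernels (VanRaden genomic
    relationships, nine-neighbour spatial smoothing, environmental-covariate and
    genomic-by-environmental Hadamard kernels), and Bayesian single- and
    multi-trait reaction-norm mixed models fitted by Gibbs sampling with
    missing-trait data augmentation. Includes leave-one-environment-out and
    leave-one-breeding-cycle-out cross-validation with trait-assisted prediction,
    predictive-ability bootstrap, variance-inflation slopes, and a synthetic
    breeding-programme data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    coda,
    lme4,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
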