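Package: mrfmix
Title: Bayesian Restoration of Low-Count Emission Images with Markov
    Random Field Mixture Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hierarchical Bayesian deblurring and denoising of low-count
    radionuclide (planar gamma-camera) images under a Poisson counting
    likelihood.  Provides homogeneous first-order Markov random field
    priors with absolute-value (Laplace) or quadratic (Gaussian)
    potentials, and a locally adaptive mixture prior in which a latent
    binary spatial factor selects, pixel by pixel, between an
    edge-preserving Laplace term and a smoothing Gaussian term.
    Posterior sampling uses Metropolis-within-Gibbs with adaptive
    proposal scaling toward the 0.234 acceptance-rate optimum.  Includes
    synthetic phantom generators, a point-spread-function forward model,
    region-of-interest evaluation tools, hyperparameter sensitivity
    sweeps, and a latent-label classifier benchmarked against k-means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    generics,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    tiff,
    yaml,
    dplyr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
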