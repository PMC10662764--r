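Package: wmprior
Title: Attractor Models of Prior Learning and Bias in Working Memory
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models of systematic bias in delayed-estimation working memory
    arising from learned environmental priors. Implements drift-diffusion
    particle models on a circular feature space with static and
    experience-dependent energy landscapes, Fokker-Planck propagation of
    response densities, distortion metrics, a stochastic neural field model
    with presynaptic plasticity together with its low-dimensional reduction,
    synthetic delayed-estimation sessions emulating a two-item color task,
    and a cross-validated model-fitting and model-selection pipeline for
    behavioral response data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
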