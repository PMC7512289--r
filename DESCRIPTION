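Package: vcgpdm
Title: Variational Coupled Gaussian Process Dynamical Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns modular movement primitives as coupled latent
    dynamical systems with Gaussian-process transition, coupling and
    kinematics functions.  Inference maximizes a collapsed evidence lower
    bound over inducing points and a factorized Gaussian posterior on the
    latent trajectories; per-part predictions of the latent state are
    fused by a product of experts with learned coupling variances.
    Includes deterministic trajectory generation, dynamic-time-warping
    evaluation, a synthetic coupled-system data generator, and modular
    recombination of trained parts into new models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
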