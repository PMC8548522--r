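Package: fbmtrack
Title: Gaussian Process Inference of Anomalous Diffusion from Particle
    Trajectories
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates apparent diffusion coefficients and anomalous
    exponents from noisy, occluded single-particle tracking data by
    modeling whole trajectories as Gaussian processes with a fractional
    Brownian motion kernel. Supports per-point localization errors,
    interpolation of missing positions with credible bands, correction
    for common substrate motion shared by multiple particles in the same
    cell, Metropolis-Hastings posterior sampling, exact trajectory
    simulation, reference mean-squared-displacement and
    displacement-distribution estimators for benchmarking, model-adequacy
    diagnostics (velocity autocorrelation, displacement self-similarity,
    variance decomposition), sub-pixel spot refinement by 2D Gaussian
    fitting, and two-channel affine image alignment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
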