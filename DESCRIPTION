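Package: cntvd
Title: Diffusion Tensor Distributions from Constrained Normal Tensor-Variate Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation of intravoxel diffusion tensor
    distributions (DTDs) for multidimensional diffusion MRI. Models the DTD as
    a six-dimensional Gaussian over diffusion tensor components constrained to
    the positive-semidefinite cone (the constrained normal tensor-variate
    distribution), generates the magnitude MR signal it produces under
    arbitrary rank-1/rank-2 b-matrix encoding by Monte Carlo integration, and
    inverts noisy signals with a nested-symmetry, BIC-selected estimator of
    the mean diffusion tensor and its fourth-order covariance tensor.
    Includes synthetic DTD phantom motifs, compressed-sensing style b-matrix
    designs, Rician noise simulation, microstructural heterogeneity stains
    (size, shape and orientation variance, micro-FA, micro-ODF entropy) and
    spherical glyph surfaces exportable as meshes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    pracma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
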