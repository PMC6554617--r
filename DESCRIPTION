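Package: shapeappear
Title: Unsupervised Diffeomorphic Shape and Appearance Modelling of Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns a generative shape and appearance model from a collection
    of 2D or 3D images without annotations.  Each image is explained by a low
    dimensional latent code that drives both an additive appearance
    perturbation of a mean template and a diffeomorphic deformation obtained
    by geodesic shooting of a latent-weighted initial velocity field.  Model
    fitting alternates Gauss-Newton updates of the template and the
    appearance and velocity bases with latent updates under a variational
    Wishart prior on the latent precision, and an orthogonalisation step that
    keeps the factorisation well conditioned.  Gaussian, Bernoulli and
    categorical noise models are provided, all with missing-voxel support, as
    are downstream tools: encoding of new images, generative classification
    by Laplace model evidence, sampling, imputation of missing regions and
    overlap metrics.  Sobolev regularisation operators (membrane, bending,
    linear-elastic and divergence penalties) are diagonalised by the FFT on a
    periodic lattice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    Rcpp,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
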