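Package: latentord
Title: Generalized Linear Latent Variable Models for Model-Based Ordination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits generalized linear latent variable models (GLLVMs) to
    multivariate community data for joint species distribution modelling and
    model-based unconstrained, constrained, and concurrent ordination.
    Estimation uses Gaussian variational approximations, with closed-form
    lower bounds where available and an extended second-order variational
    approximation for arbitrary response families, including overdispersed
    and zero-inflated counts and sparse percent-cover distributions (beta,
    hurdle beta, ordered beta). Supports structured community-level row
    effects for nested sampling designs, temporally and spatially correlated
    latent variables, trait-based fourth-corner terms, and phylogenetically
    structured species random effects with a nearest-neighbour sparse
    approximation. Includes information criteria, Wald inference,
    randomized quantile residuals, variance partitioning, ordination
    extraction with uncertainty regions, and a synthetic community-data
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
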