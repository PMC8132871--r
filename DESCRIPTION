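Package: desp
Title: Deep Enhanced Sampling of Conformation Spaces with Latent-Space Biasing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enhanced sampling of molecular conformation spaces in which a
    variational autoencoder (VAE), trained on cosine/sine features of protein
    dihedral angles, supplies per-frame latent Gaussian distributions. The
    Kullback-Leibler divergence between the latent distribution of the current
    conformation and those of previously sampled conformations defines a
    repulsive biasing potential that steers the dynamics away from visited
    states. The package provides dihedral featurization from PDB structures,
    the VAE and its training protocol, the biasing potential and its exact
    gradient, an overdamped Langevin engine on periodic model potentials so the
    whole method runs at desk scale, trajectory reweighting to recover unbiased
    free-energy profiles, dihedral PCA, and a synthetic generator of metastable
    dihedral dynamics for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
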