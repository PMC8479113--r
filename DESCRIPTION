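Package: hexadyn
Title: Comparative Dynamics Analysis of Hexameric Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing the conformational dynamics of two states of
    an oligomeric protein from molecular dynamics trajectories: robust
    fraction-based core superposition, conventional RMSD/RMSF/radius of
    gyration, dynamic cross-correlation matrices of C-alpha displacement
    vectors, essential dynamics (coordinate PCA) with eigenvector dot-product
    matrices and RMSIP subspace overlap, Shrake-Rupley solvent-accessible
    surface area and buried interface area, grid-based solvent cavity
    detection with opening frequencies and cumulative volumes, tunnel finding
    with clearance profiles, bottleneck radii and exp(-cost) throughput
    scores, and a convolutional variational autoencoder that embeds per-frame
    residue distance matrices into a latent space for state discrimination.
    Includes a seeded synthetic hexamer-trajectory generator with planted
    collective modes and toy geometries with analytic ground truth, used
    throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    cluster,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
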