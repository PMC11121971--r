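Package: oligodeg
Title: Structure-Based Screening of Oligoester Marine Biodegradability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A screening pipeline linking oligoester chemical structure to
    marine biodegradability. Builds tetramer model structures of condensation
    oligomers (oligoesters and oligoamides) from a monomer registry, computes
    GRID/VolSurf-style molecular interaction field (MIF) descriptors from
    seeded 3D conformers (hydrophilic volumes, capacity factors, integy
    moments, surface areas, logP, acidity and polar/apolar attraction-energy
    descriptors), and models them with PCA, K-means clustering and NIPALS
    partial least squares with leave-one-out Q2. Also provides OECD-306-style
    respirometry arithmetic (theoretical oxygen demand, blank correction,
    degradation degree time courses), electrospray mass-spectrometry oligomer
    arithmetic (number- and weight-average molecular weights, dispersity,
    sodium-adduct series prediction and peak assignment), and seeded synthetic
    data generators for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit (3D conformer embedding),
    OpenBabel (via ChemmineOB)
Config/testthat/edition: 3
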