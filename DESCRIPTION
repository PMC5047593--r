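Package: idspert
Title: Structural Perturbation Analysis of Missense Mutations in
    Iduronate 2-Sulfatase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the structural impact of missense mutations by
    comparing wild-type and mutant protein coordinate models. Superposes
    each mutant onto the wild type by least-squares fitting on the
    C-alpha atoms (Kabsch algorithm), counts the atoms displaced beyond a
    cutoff distance in the main chain, the side chain and the active
    site, computes the all-atom root-mean-square distance, and bins
    per-atom displacements into colour classes for visualisation.
    Includes a Shrake-Rupley solvent-accessible surface area engine, a
    packaged catalogue of 131 iduronate 2-sulfatase (IDS) missense
    mutations with severe/attenuated MPS II phenotype labels and their
    structural metrics, phenotype-group statistics based on Welch's
    t-test, and seeded generators of synthetic structure pairs and
    mutation tables with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
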