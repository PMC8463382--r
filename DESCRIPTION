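Package: neetkit
Title: Redox-State Analysis Toolkit for NEET-Protein [2Fe-2S] Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the oxidized and reduced states of
    protein-bound [2Fe-2S] clusters of the NEET family. Provides Gaussian
    cube input/output and grid algebra for difference electron densities
    and per-atom charge integration; detection of [2Fe-2S] binding sites in
    PDB structures and construction of truncated quantum-chemistry models;
    Seminario bond force constants from Cartesian Hessians and restrained
    electrostatic-potential (RESP) charge fitting with Merz-Kollman probe
    shells; weighted chi-squared coevolution scoring of multiple sequence
    alignments with a structure-aware allostery screen; GROMOS-style
    conformational clustering of trajectory snapshots; and first-order
    kinetic analysis of 458-nm absorbance decay traces for cluster
    lability. Seeded synthetic-data generators with machine-readable
    ground truth replace the quantum-chemistry and molecular-dynamics
    engines and the plate reader, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
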