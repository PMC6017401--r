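Package: CavityRigidity
Title: Rigidity Analysis of Protein Surface Cavities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for surveying the mechanical rigidity of protein surface
    cavities and interior voids. Builds body-bar mechanical models from
    protein chain structures (covalent, hydrogen-bond and hydrophobic
    constraints), decomposes them into rigid clusters with a (6,6) pebble
    game, detects cavities on a volumetric solvent-excluded-surface grid
    with triangulated surface-area measurement, aggregates per-residue
    evolutionary-trace conservation scores, associates cavities with rigid
    clusters through shared atoms, and computes the survey metrics and
    correlation analyses relating cavity geometry to rigidity. Includes
    generators for synthetic structures with known rigidity and cavity
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Rcpp, bio3d, xml2, jsonlite, MASS,
    minpack.lm, parallel
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
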