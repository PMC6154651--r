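Package: esterlib
Title: Diversity-Driven Design of Triterpenoid 3-O-Ester Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building diversity-oriented combinatorial ester
    libraries on a triterpenoid scaffold, as used in virtual screening for
    nuclear-receptor ligands.  Provides a light molecular-graph model backed
    by OpenBabel structure I/O, Lipinski-style descriptor filtering with an
    editable structural-alert catalogue, functional-class circular
    fingerprints (FCFP_4 style) with Tanimoto-based MaxMin diversity
    clustering and representative selection, combinatorial 3-O-ester
    enumeration with exact-mass and ESI adduct m/z bookkeeping, ranking of
    externally produced docking scores, and a seeded synthetic
    carboxylic-acid library generator with ground-truth labels for
    end-to-end validation of the funnel.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
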