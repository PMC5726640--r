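Package: glycotop
Title: Carbohydrate Topology and Parameter Files for NMR Simulated Annealing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preparing and validating CNS/XPLOR-dialect carbohydrate
    topology and parameter files for NMR structure calculation by simulated
    annealing. Reads and writes the topology (.top) and parameter (.param)
    dialect, harmonizes bonded force constants to the values used for
    protein and nucleic acid calculations, generates O- and S-glycosylation
    and glycosidic-linkage patches, and redefines chiral-center IMPROPER
    terms over the four tetrahedral vertex atoms (hydrogen included) so that
    annealing cannot trap a hydrogen in the mirror-flipped position. A small
    Cartesian energy model, minimizer and Metropolis annealer demonstrate the
    flip trap and its removal. Ensemble analysis utilities compute glycosidic
    phi/psi torsion statistics, sugar heavy-atom ensemble RMSD after optimal
    superposition, Cremer-Pople ring pucker classification, and XPLOR-style
    distance-restraint counts on multi-model PDB ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
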