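Package: condock
Title: Contact-Constrained Rigid-Body Protein Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts inter-protein residue contacts from paired multiple
    sequence alignments with a Naive Bayes classifier over equal-width
    discretized sequence and surface descriptors, and uses the top-ranked
    contacts as distance constraints that prune a grid-based rigid-body
    docking search. Includes solvent-accessible surface area estimation,
    surface-residue candidate selection, neighborhood-aggregated alignment
    descriptors, beam-style forward feature selection scored by
    cross-validated R-precision, constraint-propagated translational
    scanning with per-constraint model sampling, and CAPRI-style model
    assessment (ligand and interface RMSD, acceptability, gain statistics).
    Seeded synthetic generators provide toy complexes, paired alignments
    with planted coevolution signal, and labelled feature tables so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
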