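Package: specscore
Title: Side-Chain-Orientation-Aware Protein Model Similarity Scoring
Version: 0.1.0
Authors@R:
    person("specscore", "developers", email = "specscore@example.org",
           role = c("aut", "cre"))
Description: Superposition-based similarity scoring of predicted protein
    structural models against native reference structures. Combines
    GDT-style alpha-carbon distance scoring with side-chain distance and
    side-chain orientation terms (two planar angles and one dihedral) in a
    united-residue representation, where each residue is reduced to its
    alpha carbon plus the centroid of its side-chain heavy atoms. Also
    provides chi1 torsion-angle extraction with angular RMSD evaluation, a
    fixed-column PDB reader/writer restricted to heavy atoms, an LGA-style
    iterative multi-superposition search, deterministic synthetic
    model/native fixture generators, and command-line entry points with
    TSV/JSON reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
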