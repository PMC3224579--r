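Package: sdrcov
Title: Specificity Determining Residues from Covariation Between Domain
    Alignments and Binding Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate specificity determining residues (SDRs) in
    peptide recognition domains (PDZ, SH3, kinase and similar families) by
    scoring the covariation between sites of a multiple sequence alignment of
    the domains and positions of their aligned bound-peptide position weight
    matrices.  Implements sequence-weighted entropies, joint entropy, mutual
    information and the uncertainty coefficient, chi-square and permutation
    significance tests, site filtering, covariation-weighted prediction of
    binding profiles with left-out validation, and evaluation of scores
    against residue distances in co-crystal structures.  Includes a synthetic
    data generator with planted covarying site pairs and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
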