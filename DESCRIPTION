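Package: erdesign
Title: Rational Design of Estrogen Receptor Ligand-Binding-Domain Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-guided redesign of the estrogen receptor
    alpha ligand binding domain (and, by extension, other ligand binding
    proteins). Extracts ligand binding pockets from PDB-format complexes by
    distance cutoff, profiles residue conservation at pocket positions across
    ortholog alignments, enumerates natural-variant candidate mutations,
    models point mutants by rotamer-library side-chain substitution with
    van der Waals clash scoring, and fits the downstream validation assays:
    one-site competition logistic curves for fluorescence-polarization IC50
    determination, Boltzmann two-state thermal melts for Tm, and
    cross-receptor fold-change classification. Seeded synthetic-data
    generators make the full workflow testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    minpack.lm,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
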