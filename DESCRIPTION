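Package: bioactlink
Title: Cross-Linking Protein-Ligand Structures with Bioactivity Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Automated curation pipeline that links protein-ligand complex
    structures in PDB format to tabular bioactivity records of the kind
    exported from ChEMBL. Extracts candidate ligands with consistency
    checks and descriptors, canonicalizes small molecules and grades their
    correspondence on a five-level InChI/SMILES scale, aligns structure
    chains against target component or assay-variant sequences to compute
    a coverage-weighted identity score with Gold/Silver/Bronze quality
    tiers, counts binding-site mutations, selects the single best
    bioactivity target per structure or per structure-ligand pair through
    a deterministic filter cascade with a full audit trail, and assembles
    the four linked-table variants via full outer joins with merge
    indicators. Ships a synthetic-scenario generator so the whole pipeline
    is testable offline with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (the obabel executable) for molecule
    canonicalization.
Config/testthat/edition: 3
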