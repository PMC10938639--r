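Package: pfastriage
Title: In Silico Triage of PFAS Chemicals Against Nuclear Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable re-implementation of a virtual-screening triage
    pipeline for per- and polyfluoroalkyl substances (PFASs) against ten
    nuclear receptors. Provides library curation with auditable inclusion
    rules (perfluorinated-unit and fluorine-count filters, InChIKey
    deduplication), reference-anchored shortlisting of docking and MM-GBSA
    binding free-energy scores, a percent-change binder-strength classifier,
    machine-learning-gated consensus active calling, an ordered
    substructure-rule PFAS taxonomy, self-organizing-map projection of
    chemical space over ECFP4 fingerprints, residue-level protein-ligand
    interaction fingerprints, and a seeded synthetic-data generator that
    stands in for commercial docking and machine-learning outputs so every
    stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
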