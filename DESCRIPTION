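Package: massqa
Title: Single-Model Protein Quality Assessment with Knowledge-Based Statistical Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the global quality (GDT-TS) of individual protein 3D
    models without needing a pool of alternative models. Implements a family
    of ten knowledge-based statistical potentials (pseudo-bond angle, torsion
    angle, centrosymmetric burial, accessible-surface at residue and atomic
    level, distance-dependent, sequence-separation-dependent,
    contact-dependent, relative solvent accessibility, and volume-dependent),
    with reference states counted from a user-supplied set of experimental
    structures. A 70-feature global descriptor combines these potentials with
    secondary-structure and solvent-accessibility agreement scores, pseudo
    amino acid composition, radius of gyration, residue contact statistics
    and optional external energy scores; a random-forest regressor maps the
    descriptor to GDT-TS. Also provides the CASP quality-assessment
    evaluation statistics (Fisher-z weighted mean per-target Pearson
    correlation, average loss, average GDT-TS deviation, MCC and ROC AUC at
    the GDT-TS 50 threshold) and a synthetic decoy generator so the whole
    pipeline can be exercised end-to-end without external data.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
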