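Package: proqr
Title: Single-Model Protein Model Quality Assessment with Per-Residue
    S-Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts local (per-residue) and global correctness of protein
    structure models from a single model, without access to the native
    structure. Per-residue quality is the S-score, predicted by linear
    support-vector regression on windowed structural features (atom-atom and
    residue-residue contact distributions, solvent exposure patterns,
    secondary structure) combined with sequence-derived predictions (PSSM
    profile weighting, information per position, predicted secondary
    structure and burial). Includes the MaxSub-style superposition machinery
    that defines the S-score target function and GDT_TS, a Pcons-style
    structural consensus scorer with the linear single-model/consensus
    combination, the benchmark statistics used to evaluate such methods, and
    a synthetic fixture generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
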