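Package: idrbench
Title: Benchmarking AlphaFold2-Derived and Sequence-Based Intrinsic Disorder Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation machinery for residue- and protein-level intrinsic
    disorder prediction. Reads CAID-style reference annotations and per-residue
    prediction files, converts AlphaFold2 outputs (pLDDT confidence scores and
    windowed relative solvent accessibility) into disorder propensities,
    calibrates binary predictions to the native number of disordered residues,
    computes ROC/precision-recall and confusion-matrix metrics together with
    disorder-content and fully-disordered-protein evaluations, stratifies
    proteins by disordered-region type (short, long, binding, non-terminal,
    fully disordered), performs resampling-based significance comparisons
    between predictors, derives sequence-based markers that identify proteins
    where structure-derived predictions are competitive, and generates
    synthetic benchmark data with controllable class-conditional score
    distributions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    jsonlite,
    nortest
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
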