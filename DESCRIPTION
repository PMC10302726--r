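Package: glycosurv
Title: Plasma Glycoproteomic Survival Biomarker Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating prognostic classifiers from
    targeted plasma glycoproteomics panels with right-censored survival
    endpoints. Implements pooled-QC within-run drift correction, heavy
    standard peptide quantification, glycopeptide relative abundance and
    site-occupancy normalization, occupancy-weighted glycan monomer-weight
    features (fucosylation signatures), univariate age- and sex-adjusted Cox
    screening with Benjamini-Hochberg control, repeated cross-validated
    L1-penalized Cox classification with concordance-maximized risk-score
    dichotomization, and layered Kaplan-Meier and hazard-ratio evaluation.
    Includes a synthetic cohort simulator with planted hazard effects so the
    whole pipeline is testable without access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
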