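Package: seroquant
Title: Serum Biomarker Discovery and Verification by Spectral Counting,
    Immunoassay Scoring and Targeted Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested computational chain for serum biomarker studies built
    around shotgun and targeted proteomics. Covers target-decoy filtering of
    peptide-spectrum matches with per-charge Xcorr thresholds and naive
    protein-level false discovery rate estimation; label-free quantification
    by spectral counting with the relative enrichment factor Re, permutation
    ANOVA/t tests, log2-quantile normalization, hierarchical clustering and
    PCA; receiver-operating-characteristic analysis and logistic-regression
    biomarker panels; tissue-microarray quick scoring (Q = P x I) and
    western-blot densitometry normalization against a pooled calibration
    sample; and stable-isotope-dilution multiple-reaction-monitoring
    quantification with base-3 dilution calibration curves, limit of
    quantification/detection rules and absolute serum concentrations.
    Includes seeded synthetic-data generators that emulate the cohort
    structure of a lung-cancer serum study so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pROC
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
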