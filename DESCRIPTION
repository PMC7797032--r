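Package: mendelscan
Title: Microhomology-Mediated Repair-Outcome Prediction and Evaluation for
    CRISPR Double-Strand Breaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts which nuclease-induced DNA double-strand breaks are
    likely to be repaired into a single predominant allele by
    microhomology-mediated end joining (MMEJ). Enumerates and scores
    candidate microhomology deletion patterns around a cut site, computes
    the competition ratio between the top two patterns, and classifies
    sites as predominant-MMEJ-allele (PreMA) reagents. Also provides PAM
    scanning for SpCas9 (NGG) and Cas12a (TTTV), ground-truth labelling of
    amplicon repair-read pools via single-indel alignment, a combined
    deletion-plus-insertion frameshift caller, classifier evaluation
    (confusion metrics, truncated ROC sweeps, logistic and
    gradient-boosting baselines), early coding-region knockout screens,
    and a seeded synthetic-data generator with analytically known labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
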