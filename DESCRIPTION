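Package: emdeepsd
Title: Signal-Decomposition Deep Learning for cfDNA End-Motif Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cancer-versus-control classification from plasma cell-free DNA
    (cfDNA) 4-mer end-motif profiles. Extracts 256-motif end-motif profiles
    from aligned fragments and a reference genome; decomposes each profile by
    singular spectrum analysis (SSA) and empirical mode decomposition (EMD);
    computes motif diversity scores on the decomposition subsequences
    (MDS-SDs) and founder-profile contributions by non-negative least
    squares; stacks five machine-learning base learners per subsequence; and
    trains an LSTM/self-attention meta-network on the stacked out-of-fold
    probabilities. Includes evaluation statistics (sensitivity, specificity,
    accuracy, F1, AUC with DeLong machinery, per-motif Wilcoxon scans) and a
    synthetic-profile generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    nnet,
    pracma,
    pROC,
    Biostrings
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
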