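Package: rpemhc
Title: Pan-Specific MHC-Peptide Binding Affinity Prediction via Residue-Pair Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the binding affinity between MHC molecules and peptides
    with a pan-specific deep model that encodes each MHC pseudo-sequence /
    peptide pair as a 34 x 20 residue-residue interaction matrix and learns
    from it with stacked multi-scale convolutions, parallel LSTM blocks and a
    binding-core-width convolution, trained by mean-squared error on
    log-transformed IC50 values. Includes the IC50 transforms, cross-validation
    and leave-one-molecule-out protocols, ensembling, an evaluation suite (AUC,
    PRC, PCC, PPV, F1, sensitivity, Frank epitope ranking), sliding-window
    binding-core localisation, motif frequency-matrix extraction, a planted-motif
    synthetic data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    generics,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
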