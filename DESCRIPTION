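Package: mirstress
Title: Predict Abiotic Stress-Responsive Plant miRNAs from Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes mature and precursor microRNA sequences into pseudo
    K-tuple nucleotide composition (PseKNC) feature vectors, ranks features
    by support-vector-machine recursive feature elimination (SVM-RFE),
    trains a radial-basis-function SVM on class-balanced data, and
    evaluates predictions of abiotic stress responsiveness with stratified
    k-fold and leave-one-out cross-validation and a seven-metric suite
    (sensitivity, specificity, balanced accuracy, precision, F-score,
    auROC, auPRC). Includes a first-order Markov sequence simulator with a
    tunable class-separation knob so the whole pipeline is testable
    without external data, and a command-line interface over the same
    functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'classifier.R'
    'utils.R'
    'evaluation.R'
    'feature-selection.R'
    'mirstress-package.R'
    'pipeline.R'
    'plots.R'
    'properties.R'
    'pseknc.R'
    'sequence-io.R'
    'simulate.R'
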