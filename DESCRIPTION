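Package: recspot
Title: Prediction of Meiotic Recombination Hotspots from DNA Sequence Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies DNA sequences as meiotic recombination hotspots or
    coldspots from sequence composition alone. Implements gapped dinucleotide
    composition, reverse-complement (canonical) k-mer composition and pseudo
    trinucleotide composition encodings, SVM-based recursive feature
    elimination, a weighted hybrid feature combination rule, a feed-forward
    neural network classifier trained by backpropagation, baseline classifiers
    (RBF SVM, k-nearest neighbours, random forest), stratified k-fold
    cross-validation with hotspot-centric performance metrics (ACC, SN, SP,
    MCC) and ROC/AUC, and a seeded synthetic two-class sequence generator with
    a controllable planted trinucleotide signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
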