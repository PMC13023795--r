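Package: ecgmi
Title: Myocardial Infarction Detection from Single-Lead ECG via Hybrid
    Wavelet/EMD Entropy Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reusable pipeline for binary myocardial-infarction (MI)
    detection from single-lead (Lead II) electrocardiograms sampled at
    1000 Hz.  Records are denoised by six-level Daubechies-6 wavelet
    thresholding, cut into fixed 10,000-sample segments and min-max
    normalized; each segment is decomposed into 13 signal groups (the
    original signal, six wavelet detail bands D1-D6 plus approximation
    A6, and five empirical-mode-decomposition intrinsic mode functions);
    30 features (7 time-domain statistics and 23 entropy/complexity
    measures) are extracted per group, giving up to 390 features per
    segment; a binary particle swarm optimizer selects a parsimonious
    discriminative subset; and bagged trees, RBF support vector
    machines, a feed-forward neural network and k-nearest-neighbour
    classifiers are evaluated with stratified 10-fold cross-validation,
    reporting accuracy, recall, specificity, PPV and NPV with MI as the
    positive class.  A seeded synthetic Lead-II-like ECG generator makes
    the whole pipeline testable without any data download; an adapter
    for WFDB-format records is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    randomForest,
    e1071,
    nnet,
    class,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
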