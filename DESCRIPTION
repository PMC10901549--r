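Package: flimclass
Title: Metabolic Phenotype Classification from NAD(P)H Fluorescence
    Lifetime Decay Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for single-cell metabolic phenotyping from raw
    time-correlated single-photon counting (TCSPC) fluorescence lifetime
    decay image stacks (temporal point spread functions, TPSF). Includes a
    synthetic TCSPC data generator with bi-exponential NAD(P)H decays,
    instrument-response convolution and Poisson photon noise; classical
    IRF-convolved bi-exponential decay fitting and mean-lifetime imaging;
    the pre-processing chain used for cell-level classification (entropy
    quality filtering, spatial standardisation, temporal down-sampling);
    3D convolutional neural networks (LeNet- and ResNet-style) that
    classify glycolysis, oxidative phosphorylation and glutaminolysis
    directly from X-Y-T photon-count stacks; and the associated evaluation
    metrics (ROC/AUC, macro F1, phenotype fractions, t-SNE embeddings).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
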