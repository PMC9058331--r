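Package: spectropath
Title: Infrared Spectral Histopathology of Colonic Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of Fourier-transform infrared (FTIR)
    hyperspectral images of colonic tissue for spectral histopathology.
    Provides a synthetic tissue-cohort generator with known ground truth,
    extended multiplicative signal correction (EMSC) for digital
    de-paraffinization, baseline removal and normalisation, quality
    filtering, per-image K-means segmentation into histology classes with
    digital staining and centroid dendrograms, a PCA - ANOVA - LDA
    classifier with leave-one-sample-out cross-validation and majority-vote
    sample calls, and evaluation via confusion matrices, one-vs-rest
    sensitivity/specificity and ROC/AUC.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    ape,
    pROC,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
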