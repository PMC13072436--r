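Package: glomint
Title: Integrated Imaging Mass Spectrometry and Multiplexed
    Immunofluorescence Profiling of Glomerular Cell Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining in situ molecular markers of kidney
    glomerular cell types by fusing high spatial resolution MALDI imaging
    mass spectrometry (IMS) with multiplexed immunofluorescence (MxIF)
    microscopy of the same tissue section. MxIF pixel signatures are
    clustered into subglomerular segments by k-means, segments are named
    by cell type from standardized antibody intensity profiles, labels
    are transferred to coregistered IMS pixels, and per-segment lipid
    signatures are mined with gradient-boosted classifiers interpreted
    by Shapley additive attributions, yielding ranked, sign-annotated
    marker candidates per segment. Includes affine landmark registration,
    per-segment average and difference mass spectra, an intrasample
    deep-versus-superficial glomerulus comparison, and a synthetic
    paired-data generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    xml2,
    tiff,
    xgboost,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
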