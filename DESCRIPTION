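Package: punctaging
Title: Quantification of Nucleo-Cytoplasmic Puncta Redistribution in Aging Brain Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantitative fluorescence microscopy of
    subcellular protein puncta in brain tissue sections, built around the
    age-associated redistribution of the translesion-synthesis polymerase
    POLK between nuclear speckles and cytoplasmic granules. Provides a
    synthetic tissue-image generator with ground truth, Nissl-based soma
    detection and nucleus/cytoplasm partitioning, marker-based cell-class
    gating (interneuron, pyramidal, non-neuronal, microglia) with
    microglia-association scoring, per-compartment puncta detection and
    per-object co-marker intensity measurement, clustered statistical
    inference (covariate-adjusted contrasts with effect sizes, generalized
    estimating equations with cluster-robust errors, subsampled rank
    tests), and ensemble age/cell-class classifiers with one-vs-rest AUROC
    and feature importance.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    emmeans,
    jsonlite,
    pROC,
    randomForest,
    stats,
    tiff,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
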