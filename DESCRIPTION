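Package: CalciPop
Title: Subpopulation Analysis of Calcium Imaging in Mixed Retinal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-lapse Fluo-4 calcium imaging of
    heterogeneous (mixed neuronal/glial) cultures under control and
    chemically mimicked hypoxia. Provides principal-component based
    segmentation of cells from fluorescence movies, per-cell trace
    extraction, second-order polynomial photobleaching correction,
    deltaF/F0 normalisation, calcium spike detection, k-means clustering
    of (spike count, Ca2+max) features into four activity classes,
    boundary-based classification of treated populations, subsampled
    subpopulation profiling with Kruskal-Wallis condition comparisons,
    and companion 2^-ddCt qPCR fold-change and resazurin viability
    computations. A ground-truthed synthetic-data generator emulating
    the population structure of mixed retinal cultures makes every
    pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    tiff,
    yaml,
    jsonlite,
    ggplot2,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
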