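Package: bmatlas
Title: Spatial Risk Mapping of Brain Metastases in Atlas Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for voxelwise spatial risk analysis of brain metastases in a
    common atlas space: a synthetic brain phantom and inhomogeneous point-process
    lesion simulator, lesion morphometrics (volume, Wadell sphericity, centroid
    distance to the gray-white matter interface, atlas membership), cumulative
    voxelwise risk maps with regional contribution and density statistics,
    comparison of interface proximity against a tissue-morphology null via the
    1-D Wasserstein distance and Wilcoxon signed-rank test, normalized-perfusion
    subspace analysis, and expected-coverage tradeoffs for function-sparing
    whole-brain radiotherapy target volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
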