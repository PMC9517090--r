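Package: orthoicp
Title: Landmark-Free Accuracy Evaluation of Orthognathic Surgical Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how accurately a virtual orthognathic surgical plan
    was transferred to the operating room by comparing the planned and
    postoperative craniofacial surface models without cephalometric
    landmarks. Reads and writes STL surface meshes, registers the
    postoperative model onto the plan over a stable cranial reference region
    using PCA initial alignment followed by trimmed point-to-mesh iterative
    closest point (Kabsch/SVD inner solver, exact point-to-triangle
    correspondences), and measures the repositioned maxillary region
    point-to-surface against the plan. Reports the deviation field, its RMS
    "3D error" against a clinical +/-2 mm acceptability band, deviation
    colormaps (PLY), operator averaging, group summaries, normality checks
    and two-group comparisons. Includes a synthetic skull-phantom generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
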