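Package: ivmmotility
Title: Motility Analysis for Intravital T-Cell Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-photon intravital microscopy recordings
    of T cells in tumor-invaded tissue. Computes per-track motility statistics
    (speed, displacement, straightness, speed variation, arrest coefficient),
    classifies track behavior into five actions (flowing, directed, patrolling,
    focused patrolling, arrested) via sliding-window tracklet features,
    multivariate dynamic-time-warping distances, UMAP embedding and k-means
    clustering, and quantifies pixel-level motility with dense optical flow
    over concentric erosion bands of a tumor region of interest. Ships a
    synthetic-data module that simulates persistent-random-walk track cohorts
    from the five behavioral archetypes and renders them as noisy timelapse
    images, providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    uwot,
    EBImage,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
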