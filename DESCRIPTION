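Package: rootaxis
Title: Angular Error of Software-Predicted Tooth Root Axes Against
    CBCT-Derived Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end validation pipeline for the accuracy of tooth root
    long axes predicted from crown-only digital dental models, measured
    against root axes extracted from cone-beam computed tomography (CBCT)
    surfaces.  Provides STL triangle-mesh input/output, orthogonal 3D line
    fitting, mesh cross-sectioning with equidistant outline landmarking,
    area-uniform surface sampling, landmark (Kabsch) initialization plus
    trimmed iterative-closest-point rigid registration, binary voxelization
    with partial-volume-aware isosurface extraction, a parametric generator
    of synthetic anterior-tooth phantoms with known ground-truth axes and
    controllable injected angular error, and the accompanying statistical
    battery: Dupont-Plummer paired sample size, Shapiro-Wilk screening,
    Mann-Whitney and Kruskal-Wallis group comparisons with Bonferroni
    adjustment, paired t systematic-error checks, and Bland-Altman limits
    of agreement.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
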