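Package: irisopt
Title: Coverage-Volume Histogram Metrics and Iris Collimator Diameter
    Optimization for Tracked Lung Radiosurgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates robotic-radiosurgery tracking plans for lung targets with
    coverage-volume histograms (CVH) and leakage-volume histograms (LVH), and
    selects the Iris variable-aperture collimator diameter that satisfies a
    C95/C90 clinical-target-volume coverage threshold while minimizing leakage
    into surrounding normal tissue. Includes voxelized phantom generation with
    GTV-to-CTV-to-PTV margin expansion, a motion-trace simulator and CSV reader
    for per-imaging-time-point tracking errors, per-voxel coverage and leakage
    accumulation, the three-step candidate/feasibility/cost optimization, and a
    synthetic-cohort module with paired Wilcoxon and Spearman rank analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
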