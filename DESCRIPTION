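Package: sirtpartition
Title: Territorial Partition-Model Dosimetry for Yttrium-90 Radioembolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Activity planning and absorbed-dose calculation for selective
    internal radiation therapy (SIRT) with yttrium-90 microspheres. Implements
    the classical MIRD lung/normal-liver/tumor partition model and its
    generalization to arbitrary liver partitions built from arterial vascular
    territories: vessel-mask skeletonization, centerline graph extraction,
    nearest-branch territory labeling, an 11-mm beta-range margin around
    tumors, count-based uptake estimation (lung shunt fraction, tumor-to-normal
    ratio, fractional uptake), threshold-constrained prescribed-activity
    calculation, and the empirical body-surface-area method. A synthetic
    phantom generator (procedural arterial tree, ellipsoidal liver, spherical
    tumors, Gaussian point-spread blur, Poisson counts) makes the whole chain
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    igraph,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
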