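Package: orbfloor
Title: Slice-Based and Surface-Based Measurement of Orbital Floor Defect Areas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the size of orbital-floor blowout-fracture
    defects from CT-like volumes and to compare the clinically used
    slice-based linear 2D area estimate against a surface-based 3D
    measurement. Includes a synthetic phantom generator with analytically
    known defect areas, Hounsfield-unit bone segmentation, isosurface
    extraction with STL exchange, defect-rim detection with polynomial
    patch fitting and first-fundamental-form area integration, the
    per-slice mediolateral-width 2D estimator, and paired nonparametric
    cohort comparison with exact Wilcoxon signed-rank p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    mgcv,
    deldir,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
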