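Package: fermiperf
Title: Quantitative First-Pass Myocardial Perfusion Analysis by
    Fermi-Constrained Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated quantitative analysis of dynamic first-pass
    stress/rest myocardial perfusion MRI. Implements affine respiratory
    motion correction by maximization of joint correlation, contour
    delineation on a temporal maximum-intensity-projection feature image,
    AHA 16-segment mapping with coronary territories, dual-bolus arterial
    input function construction with quality control, pixel-wise
    Fermi-constrained deconvolution yielding myocardial blood flow maps,
    myocardial perfusion reserve computation with ischemia calling
    (MPR < 1.5), a synthetic perfusion phantom generator with known
    per-segment flow ground truth, and diagnostic-accuracy statistics
    (sensitivity, specificity, exact McNemar, ANOVA with Bonferroni
    correction, Fisher and chi-square tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    RNifti,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
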