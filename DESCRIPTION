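Package: dcekinet
Title: Pharmacokinetic Response Assessment for Dynamic Contrast-Enhanced MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess tumour response to neoadjuvant chemotherapy from
    dynamic contrast-enhanced MRI acquired at high spatial but low temporal
    resolution. Converts signal-intensity time courses to relative
    contrast-agent concentration, provides measured (arterial region of
    interest) and theoretical (Weinmann biexponential) arterial input
    functions, fits the Tofts/modified Kety model per curve and per voxel to
    produce Ktrans and Ve maps, classifies pre-/post-treatment kinetic
    parameter changes against pathologic response grades with cutoff rules,
    and supplies the nonparametric statistics layer (empirical ROC and
    pair-counting AUC, DeLong paired AUC comparison, Mann-Whitney and
    Kruskal-Wallis tests, exact binomial confidence intervals). Includes a
    synthetic 4D phantom and patient-cohort generator with known ground truth,
    and a packaged 24-patient reference table with a one-call reanalysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    RNifti,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
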