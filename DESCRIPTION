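Package: perfusym
Title: Mirror-Asymmetry Detection of Postictal Hyperperfusion on Brain SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects prolonged postictal hyperperfusion adjacent to a stroke
    lesion from a single postictal perfusion SPECT scan by left-right mirror
    subtraction in a symmetric standard space ("asymmetry method"), alongside
    the classic postictal-interictal (SISCOM-style) subtraction comparator.
    Provides NIfTI volume primitives (resampling, Gaussian smoothing in mm,
    mirror flipping, count normalization), deterministic rigid co-registration
    and affine anatomical standardization onto a packaged symmetric template,
    z-map cluster-extent thresholding with anatomical exclusion rules and a
    2.0 to 1.5 SD fallback, region/laterality localization on a ten-region
    atlas, diagnostic-accuracy statistics (sensitivity, specificity, ordinal
    ROC-AUC, Cohen's kappa, Wilcoxon tests), and a synthetic stroke-brain
    phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
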