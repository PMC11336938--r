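Package: nafldbis
Title: Non-Invasive Early NAFLD Detection from Multi-Frequency Bioimpedance Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates multi-frequency, multi-electrode liver bioimpedance
    measurements (Randles electrode-skin contact model plus Cole-type tissue
    dispersion), classifies the resulting 15 x 30 impedance-magnitude matrices
    with an attention-augmented residual network against a plain residual
    baseline, evaluates with a stratified 50/20/30 protocol (ROC, AUC,
    confusion matrices), and reproduces a histology-based ground-truth
    pipeline (lipid-droplet segmentation, size-binned counts, ANOVA group
    comparison) on synthetic stained-section images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
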