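Package: funduschange
Title: Unsupervised Sparse-Representation Change Detection for Retinal
    Fundus Image Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects change regions (lesions) between a registered pair of
    longitudinal retinal fundus images. The background of the current image
    is reconstructed patch-by-patch by sparse coding (LARS-lasso) over a
    local dictionary of neighbourhood patches taken from the reference
    image, so that smooth illumination differences are absorbed by the
    representation coefficients and genuine changes remain in the residual.
    Includes difference-image thresholding and morphological cleaning, an
    illumination-corrected difference pathway with mask-gated fusion for
    large lesions, pixel-wise ROC/PR/IOU evaluation, and a seeded generator
    of fundus-like synthetic image pairs with exact ground-truth change
    masks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    glmnet,
    jpeg,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
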