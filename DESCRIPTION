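Package: leafcure
Title: Recognition of Tobacco Leaf Curing States from Barn Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@leafcure.org", role = c("aut", "cre"))
Description: Multi-task ordinal classification of tobacco leaf states during
    bulk curing (yellowing, browning and drying degree) from RGB images. A
    three-branch network combines a windowed scaled-cosine-attention backbone
    with a Fourier filter branch that reads wrinkle texture from the 2-D
    spectrum of the grayscale image, and a common-colour filter branch that
    embeds the most frequent quantized colours of the centre crop. Includes a
    synthetic leaf-image generator with planted, recoverable colour and
    texture signals, a full training and evaluation pipeline (AdamW, cosine
    schedule, confusion matrices, adjacent-stage accuracy), classical
    baselines (KNN, SVM, random forest) and gradient-based saliency maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    withr,
    rlang,
    class,
    e1071,
    randomForest,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
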