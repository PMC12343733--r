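Package: biaslens
Title: Detecting, Annotating and Unlearning Spurious Shortcuts in Small Convolutional Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interpretability-driven workflow for auditing convolutional
    classifiers for spurious-correlation ("Clever Hans") behaviour and for
    removing it. The package generates controlled 2D image and 1D signal
    datasets with planted artifacts and ground-truth masks, trains small
    CNNs with a built-in layer-wise relevance propagation (LRP) engine,
    models bias concepts as concept activation vectors (CAVs) in latent
    space, surfaces shortcut behaviour by spectral clustering of relevance
    patterns and outlier analysis of concept representations, localizes
    artifacts via concept-conditioned attribution, and mitigates them with
    gradient-penalty finetuning (right-for-the-right-reasons and latent
    concept penalties) or training-free projection editing of activations.
    A metric suite (clean/biased accuracy, artifact relevance, IoU,
    retrieval AUROC/AP, TCAV sensitivity) quantifies shortcut reliance
    before and after mitigation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    mclust,
    jsonlite,
    yaml,
    png,
    tibble,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    EBImage,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
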