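Package: fruitcam
Title: Explainable CNN-Guided Tissue Sampling and Transcriptomic Comparison for Fruit Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic testbed for explainable-AI-guided
    tissue sampling in fruit disorder research. Generates labelled fruit-like
    images with planted, subtle blemishes; trains small VGG-style binary
    convolutional networks from scratch; localises class-relevant regions with
    Grad-CAM, guided backpropagation and guided Grad-CAM at any named
    convolutional layer; quantifies relevance geometry with a contour-distance
    histogram H(r,d) and extracts featured/non-featured square sampling
    windows; simulates paired negative-binomial RNA-seq counts with planted
    differentially expressed genes; and runs the two-criteria differential
    expression comparison (unpaired DESeq2, paired edgeR) with overlap,
    concordance, PCA and hypergeometric set enrichment summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    pROC,
    EBImage,
    S4Vectors,
    DESeq2,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
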