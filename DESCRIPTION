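Package: qtpcervix
Title: Quantitative Tissue Phenotype Analysis of Confocal Images for Grading Cervical Neoplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading cervical intraepithelial neoplasia (CIN) from en-face
    confocal fluorescence images of acriflavine-stained epithelium. Implements nuclei
    segmentation (derivative-of-Gaussian Canny edge detection, morphological
    reconstruction hole filling, erosion/dilation cleanup, quality filtering),
    quantitative tissue phenotype (QTP) features built on a ROI-clipped Voronoi
    tessellation and its Delaunay dual (mean nuclear area, cell density, estimated
    nuclear-to-cytoplasmic ratio, mean distance to the three nearest Delaunay
    neighbours), threshold-based three-class grading, and diagnostic-accuracy
    statistics (sensitivity/specificity with truncated integer percents, ordinal
    mid-rank Spearman correlation, one-way ANOVA with Fisher's LSD post hoc test).
    A grade-conditioned synthetic epithelium generator with exact ground truth makes
    the full pipeline testable without patient data; a published colposcopy-versus-
    histopathology contingency table ships as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    polyclip,
    purrr,
    rlang,
    spatstat.geom,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
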