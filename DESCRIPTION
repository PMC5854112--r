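Package: leafmorph
Title: Leaf-Margin Morphometrics, Alpha-Hull Dissection Index and
    Reporter-Fluorescence Quantification
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative morphometrics for leaf silhouettes and boundary
    reporter images. Computes the alpha-hull-normalized dissection index
    (the isoperimetric ratio of a leaf contour divided by that of its
    alpha-hull), detects marginal tooth and sinus landmarks from contour
    curvature, measures tooth height and blade length, builds mean
    silhouettes and developmental trajectories (local-regression curves,
    blade-length-class t-tests), and quantifies reporter fluorescence as
    seeded above-local-background zone intensity and ranked nuclear
    intensities. A parametric generator of leaf silhouettes and synthetic
    fluorescence images with exported ground truth makes every stage of
    the pipeline testable without raw micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
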