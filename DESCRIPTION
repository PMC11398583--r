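Package: wormchip
Title: Segmentation and Developmental-Toxicity Phenotyping of C. elegans
    in Microfluidic Channel Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of brightfield and fluorescence z-stacks of
    C. elegans immobilized in parallel microfluidic trapping channels. A
    seeded synthetic-scene generator emulates channel hyperstacks, ground
    truth masks and dose-response population structure; a 2.5D U-Net with a
    vision-transformer bottleneck (implemented natively, with hand-derived
    backpropagation) performs joint semantic segmentation of the worm body
    and full/partial/empty channel classification; post-processing extracts
    body length (skeleton geodesic), area and channel-height-aware volume
    plus gut autofluorescence metrics; dose-response statistics provide
    four-parameter Hill fits with EC10 confidence intervals, Tukey-fence
    outlier filtering, Welch ANOVA with Dunnett T3 post hoc tests for
    LOAEL determination, and control coefficients of variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
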