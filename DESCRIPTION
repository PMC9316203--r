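Package: stylomorph
Title: Elliptic Fourier Outline Morphometrics and Morphospace Disparity
    for Larval Head Capsules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative outline morphometrics for stylet-bearing insect
    larval head capsules. Provides a parametric generator of labelled
    head-plus-stylet outlines, readers and writers for XY coordinate,
    TPS outline and Freeman chain-code files, outline standardization
    (stylet straightening, half-mirroring, equal arc-length resampling),
    a clean-room elliptic Fourier analysis with first-harmonic
    normalization, PCA morphospace construction with effective-component
    selection, group disparity metrics (sum of variances, average
    displacement) with bootstrap and rarefaction, PERMANOVA and
    bootstrapped Bonferroni-corrected pairwise tests, and an end-to-end
    reproducible pipeline comparing fossil time slices against the
    extant fauna.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
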