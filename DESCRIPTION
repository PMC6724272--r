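Package: rhsizer
Title: Root Hair Length Profiling and Growth-Zone Modelling from Root-Tip Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures root hair (RH) length profiles from single focused
    root-tip micrographs and models them with a symmetric sigmoid to extract
    biologically meaningful parameters. The pipeline segments the root and its
    hairs with local adaptive thresholding (Bernsen and Phansalkar), extracts
    the root median line as the longest geodesic path of the root-body
    skeleton, straightens the hairs-only mask along that line, scans it with a
    non-overlapping sliding rectangular window to estimate RH length as
    thresholded area divided by window width, applies an interval max filter
    to be robust to bald spots and bent hairs, and fits the resulting profile
    in two steps with a four-parameter logistic curve. Fitted parameters yield
    mature RH length, the positions of RH initiation and growth arrest, the
    width of the RH growth region, and (given a root growth rate) an estimated
    RH growth rate. A synthetic root-tip image generator with known ground
    truth supports validation of the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
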