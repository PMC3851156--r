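Package: mfodetect
Title: Efficient Muscle Fiber Orientation Estimation in B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates muscle fiber orientation (MFO) in longitudinal B-mode
    ultrasound images of skeletal muscle. Fascicles and aponeuroses are enhanced
    with multiscale Hessian vessel-enhancement filtering, binarized with Otsu's
    method, and extracted iteratively longest-region-first: long-and-thin regions
    yield their angle directly from the moment-equivalent ellipse, while branched
    regions fall back to a Hough transform restricted to the region's own pixels.
    Includes a synthetic sonogram generator with exact ground truth (speckled,
    blurred bright bands at known angles), frame/sequence I/O, overlay plotting,
    and tidy accessors for all result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    png,
    purrr,
    readr,
    rlang,
    tibble,
    tiff,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
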