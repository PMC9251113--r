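Package: huedomains
Title: Hue-Domain Mapping and Decoding for Intrinsic Signal Optical Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intrinsic signal optical imaging (ISOI)
    experiments that map cortical hue preference in cone-opponent (DKL) color
    space. Converts trial-wise reflectance image stacks into fractional
    reflectance-change (dR/R) response maps, applies median-filter high-pass
    and smoothing, builds single-condition, subtraction and vector-sum hue
    preference maps, screens pixels with a chi-square vessel-variance rule,
    thresholds statistical maps with a cluster-extent procedure requiring
    cross-session reproduction, extracts hue domains and overlapping-domain
    hue clusters with their morphometrics, and decodes hue identity from
    binned response patterns with a cross-validated linear classifier and
    bootstrap inference. Includes a synthetic-data generator with planted
    ground truth so the whole pipeline is testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    e1071,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
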