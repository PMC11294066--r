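Package: petmoco
Title: Data-Driven Head Motion Correction for Brain PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, detection, estimation and correction of rigid head
    motion in short single-bed-position brain PET studies. Implements a
    centroid-of-distribution (COD) motion detector on 1 Hz list-mode traces,
    segmentation of a scan into motion-free frames with a 5 s rejection rule,
    ordered-subset expectation-maximization (OSEM) reconstruction under a
    per-slice parallel-beam geometry with attenuation correction,
    mutual-information rigid registration of frames, attenuation-map
    alignment, and summation into a corrected image. Ships a digital brain
    phantom and list-mode event simulator with known injected motion, and an
    ROI-based quantitative evaluation layer (cerebellum-referenced SUV-ratio
    gray-matter masking, 11-region SUV means, percent changes, motion-distance
    summaries, small/large motion classification).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
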