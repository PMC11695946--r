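Package: cochleaCa
Title: Analysis of Spontaneous Calcium Activity in the Developing Cochlea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing in vivo two-photon calcium-imaging
    recordings of the pre-hearing cochlear sensory epithelium: frame
    quality control and rigid drift correction, ROI trace extraction with
    dF/F0 normalisation, prominence-based transient detection, grouping
    of transients into single-, pair- and multi-cell events along the
    inner-hair-cell row, 3D segmentation and quantification of
    supporting-cell calcium waves, kymograph propagation-speed
    measurement, and assignment and recruitment statistics of spiral
    ganglion afferent terminals. A synthetic-movie generator renders
    GCaMP-like timelapse stacks with known ground truth so that every
    stage of the pipeline can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
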