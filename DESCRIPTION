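Package: yolowl
Title: Auditable Implementation of the YOLO-WL Wildlife Detection Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Manifest-driven construction and audit of the YOLO-WL
    convolutional detector for wildlife in UAV aerial imagery. Provides the
    network building blocks (grouped conv-BN-SiLU stems, C2f, SPPF, the
    multi-scale dilated depthwise separable convolution unit and its C2f
    integration, multi-scale large-kernel spatial attention, spatial guidance
    fusion junctions over a shallow P2-P4 pyramid, and an anchor-free
    decoupled head), exact per-layer parameter and FLOP accounting against
    the published layer table, box decoding, non-maximum suppression, and
    precision/recall/AP evaluation, plus a seeded synthetic aerial-scene
    generator so the whole kit is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
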