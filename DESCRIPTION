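Package: tableside
Title: Operating-Table Interaction Metrics from 2D Pose Tracklets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how much time operating-room personnel spend
    interacting with the operating table, from per-frame 2D human pose
    detections in the 17-keypoint COCO layout. Provides a
    confidence-prioritised greedy tracker based on object keypoint
    similarity (OKS), rule-based movement and position classification of
    subposes (wrists, shoulders, head) against annotated room regions, the
    bias-compensating interaction time-fraction metric F with overlapping
    sliding windows, detection-rate evaluation against interval
    annotations, workflow-phase stratified summaries, a synthetic
    operating-room scene generator with ground truth, and a command-line
    pipeline with colour-coded pose overlay rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
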