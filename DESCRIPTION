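Package: pigtrackr
Title: Tracking-by-Detection and Social Contact Quantification for Group-Housed Pigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies social contacts between a known number of group-housed
    pigs from per-frame keypoint detections. Implements the full
    tracking-by-detection chain: a seven-channel binary keypoint/line image
    codec with depth-first-search line extraction and orientation assignment,
    a constant-velocity Kalman-filter tracker with Hungarian data association
    and corrupted-frame fallback, proximity-region head-head and head-tail
    contact detection with a per-frame adaptive radius, weighted social
    contact networks, and the standard detection (sensitivity, precision, F1)
    and tracking (MOTA) evaluation metrics. A built-in pen simulator generates
    ground-truth trajectories, staged contact events and detector-style noise
    so every stage can be exercised without farm video; an optional toy-scale
    encoder-decoder keypoint detector is included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    png,
    EBImage,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
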