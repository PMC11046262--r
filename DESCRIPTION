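Package: arutrack
Title: Marker-Based Engagement Scoring for Rodent Go/No-Go Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores rodent engagement in nose-poking go/no-go operant tasks
    from head-mounted square fiducial markers tracked by overhead cameras.
    Provides planar pose geometry (marker center, nose-ward heading, yaw
    relative to the chamber module wall, region-of-interest membership),
    a deterministic 4x4 marker dictionary with a frame renderer and
    detector for synthetic validation, multi-camera detection fusion with
    per-frame coverage accounting, any-frame trial scoring synchronized to
    the trial timeline, a causal rectangular-kernel probability-of-engagement
    trace with threshold-crossing disengagement detection, and
    confusion-matrix validation metrics including the Matthews correlation
    coefficient. A seeded synthetic-session simulator generates ground-truth
    trial labels, per-camera detection streams with occlusion dropout, and
    rendered marker frames with optional linear motion blur, so the whole
    pipeline is testable without recorded animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
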