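Package: wagtrack
Title: Post-Processing and Behavioural Metrics for 3D Key-Point Tracking of Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning multi-camera 3D key-point tracking of freely
    moving dogs into trial-level behavioural response variables. Implements a
    geometric outlier-filter cascade (room bounds, per-frame centroid
    deviation, neighbour jumps, an iterated velocity filter) with linear gap
    interpolation, rolling-average smoothing and full data-loss accounting;
    zone-occupancy, locomotion, exploration, gaze-angle and tail-wagging
    laterality metrics for a 2 x 2 owner/stranger-presence design; an
    internal-consistency and manual-agreement validation battery; scaffolding
    for beta and linear mixed-model analyses of the resulting proportions; and
    a synthetic study generator with known ground truth so that the whole
    pipeline can be exercised and tested offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lme4,
    glmmTMB,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    car
Config/testthat/edition: 3
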