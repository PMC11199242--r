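Package: microstatr
Title: EEG Microstate Segmentation and Error-Related Negativity Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Topographic EEG microstate analysis for resting-state and
    response-locked (go/no-go) data: spatial filtering and epoch rejection,
    GFP-peak extraction, polarity-invariant and polarity-variant modified
    k-means clustering with a multi-criterion ("meta-criterion") choice of the
    number of microstate classes, two-stage resampled individual/group
    clustering, backfitting with temporal smoothing and a minimum-segment rule,
    per-state temporal statistics (GEV, duration, coverage, occurrence),
    microstate-guided scoring of the error-related negativity (ERN), robust
    (MCD) outlier screening with hierarchical regression and
    Benjamini-Hochberg correction, and a seeded synthetic-data generator with
    full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
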