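Package: eventmapr
Title: Pattern-Similarity Change Analysis of Spatio-Temporal Event Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring how learning a spatio-temporal event
    structure changes multivoxel fMRI pattern similarity, and for relating
    that change to remembered spatial and temporal distances between events.
    Implements trial-pattern extraction with nuisance regression,
    cross-correlation matrices with block exclusion, pre/post
    pattern-similarity change (PS'), Spearman model fits against behavioral
    distance matrices, shuffle-null first-level z statistics, sign-flip
    second-level tests with false discovery rate control, a whole-volume
    searchlight with max-statistic family-wise correction, and a synthetic
    data generator (routes with teleporters, distance-judgment behavior,
    picture-viewing-task recipes, and 4D volume series with implanted
    effects) so the full pipeline runs end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
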