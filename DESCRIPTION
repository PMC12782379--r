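Package: pactr
Title: Retrieve-and-Refine Prediction of Transradial Prosthetic Sockets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts a customized transradial prosthetic socket mesh from a
    3D residual-limb scan using a reference library of prosthetist-designed
    limb-socket pairs. A query limb is aligned to an anatomical frame from
    three bony landmarks, matched against length-normalized library limbs by
    mean nearest-neighbour surface distance, and the retrieved socket is
    refined by isotropic and anisotropic (anterior-posterior, medio-lateral)
    scaling. Includes the full evaluation suite used to validate such
    predictions against reference sockets: ICP co-registration and mean
    surface deviation, voxel-based signed volume differences, 100-station
    cross-sectional-area profiles with fit classification, signed-distance
    deviation maps clustered with DBSCAN and aggregated across participants
    into average unit direction vectors, and Welch/Pearson subgroup tests
    with Holm-Bonferroni correction. A seeded parametric generator of
    anatomically plausible limb-socket cohorts with known ground truth makes
    the whole pipeline testable without clinical scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
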