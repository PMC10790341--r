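Package: follicledyn
Title: Granulosa Cell Proliferation Modelling of Ovarian Follicle Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for studying ovulatory follicle selection in the
    mouse estrous cycle. Computes BrdU labeling indices from multi-class histology
    segmentation masks, applies stereological serial-section sampling and atresia
    classification rules, fits labeling-index-versus-diameter regressions, and
    implements an iterative granulosa-cell proliferation model of antral follicle
    growth (mural volume allometry V = 0.18*D^3.05, 132.6 um^3 per granulosa cell)
    used to simulate recruitment of the preovulatory cohort and the minimum estrous
    cycle length. Includes seeded synthetic-data generators (follicle populations,
    pulse-chase designs, serial-section stacks of spherical follicles, label masks)
    so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
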