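Package: camtrapdiel
Title: Diel Activity Analysis for Camera-Trap Detection Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing circadian (diel) activity patterns of
    mammals from camera-trap detection records. Enforces detection
    independence, computes sunrise/sunset times from the NOAA solar-position
    equations, expresses detections as signed offsets from the nearest solar
    anchor, partitions the 24-h cycle into dawn/day/dusk/night, classifies
    species as nocturnal, diurnal, crepuscular or cathemeral, estimates
    pairwise activity overlap with von Mises kernel densities and bootstrap
    confidence intervals, computes lagged circular cross-correlations between
    predator and prey diel profiles with a t-based significance rule, and
    compares seasonal offsets by one-way ANOVA with Tukey HSD. Includes a
    synthetic camera-trap data generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
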