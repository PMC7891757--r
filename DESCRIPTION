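Package: aoiscan
Title: Area-of-Interest Scanpath Analysis for Visual Scanning Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of visual scanning behaviour from area-of-interest (AOI)
    gaze recordings, as used in cockpit monitoring and other expertise studies.
    Converts time-stamped gaze sample streams into cleaned dwell sequences
    (minimum-dwell filtering and same-AOI merging), then computes first-order
    Markov transition matrices and their density, gaze transition entropy,
    the ambient/focal coefficient K, Lempel-Ziv complexity of the AOI
    sequence, and n-gram pattern mining with group-common pattern counts.
    Includes a cosine-distance k-nearest-neighbour classifier over flattened
    transition matrices with stratified cross-validation and an exact binomial
    chance level, flight-performance scoring (RMSE against point or band
    targets, callout-omission counting), and a seeded synthetic scanpath
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
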