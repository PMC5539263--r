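Package: copymove
Title: Screening Images for Copy-Move Manipulation and Duplicated Figures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects copied-and-pasted regions within a scientific image and
    duplicated (or cropped) figures across image pairs by exhaustively scoring
    every cyclic shift of one image over another. Three per-shift statistics
    are provided: the count of exactly identical superimposed pixels, the
    count of identical 3x3 pixel neighborhoods, and the accumulated 3x3-block
    variance of the difference image, which is invariant to constant
    brightness offsets. Conspicuous shifts are ranked after excluding trivial
    small displacements, matching regions are localized in image coordinates,
    and batch screening of image directories produces machine-readable
    reports. A seeded generator builds micrograph-like fixtures with planted
    duplications for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jpeg,
    jsonlite,
    png,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
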