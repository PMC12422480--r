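Package: vocrep
Title: Quantitative Resolution of Animal Vocal Repertoires from Call Acoustics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to resolve a putative animal vocal repertoire into an
    acoustically discriminable one. Calls are summarised by 26 band-limited
    spectral and temporal parameters plus five classical-MDS coordinates of a
    dynamic-time-warping distance matrix over dominant-frequency contours;
    per-parameter outliers are neutralised by a z-score/median rule; a
    class-weighted random forest yields out-of-bag predictions, a confusion
    matrix and an exact binomial test against chance; and a plurality rule on
    the confusion matrix decides which call types are retained and which are
    merged. A deterministic synthetic call-audio generator with a gradedness
    knob makes the full pipeline testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ranger,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rtsne,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
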