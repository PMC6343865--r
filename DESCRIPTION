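Package: whalesong
Title: Symbolic Analysis of Humpback Whale Song Phrase Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the symbolic (phrase-level) analysis of humpback whale
    song recordings logged as timed, labeled phrase events.  Implements
    delineation of phrase sequences into song fragments using start/end-label
    and phrase-recurrence rules, first-order Markov transition matrices of
    theme sequences with extraction of common full-song paths, Fisher exact
    tests of transition consistency across recording periods with
    static/shifting theme classification, token-level Levenshtein distances
    with set-median and Kohonen-median representative sequences, Levenshtein
    similarity index matrices with single-linkage clustering, Dice
    phrase-sharing indices between periods, and minimum-singer estimation
    from overlapping phrase intervals.  A synthetic song-corpus generator
    with known ground truth supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
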