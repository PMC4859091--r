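Package: stylemark
Title: Markov Style Capture, Constrained Melody Generation, and
    Style-Attribution Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Captures a keyboard improviser's style as first-order Markov
    transition statistics over chordal note events, generates new pieces from
    that style under unary positional constraints (statement, continuation,
    conclusion chunk structure) by feasibility-filtered sampling rather than
    random walks, and simulates the yes/no style-attribution experiment in
    which listeners judge whether excerpts "sound like their music".
    Includes a minimal Standard MIDI File reader/writer, a synthetic cohort
    generator (participant styles plus signal-detection responders), and the
    full nonparametric analysis pipeline: Hodges-Lehmann rank confidence
    intervals and TOST equivalence testing, Woolf homogeneity and
    Mantel-Haenszel pooled odds ratios over group strata, and the
    nonparametric signal-detection indices A' (discriminability) and B''d
    (response bias).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
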