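Package: rivalcall
Title: Dominance, Vocal Signatures and Playback Analysis for Pulsed Threat Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for rival assessment in polygynous pinniped
    colonies: Elo-rating dominance scoring of dyadic contests, pulse-train and
    spectral-quartile feature extraction from calibrated recordings of pulsed
    threat calls, permuted cross-validated discriminant classification of
    callers, Euclidean-distance stability of vocal signatures across years and
    social contexts, correlation tables linking acoustics, morphometrics and
    dominance, playback-stimulus synthesis with size-cue manipulation, and
    varimax-rotated principal-component scoring of behavioural responses.
    Includes a synthetic colony generator that emulates the statistical
    structure these analyses assume, so the whole chain is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
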