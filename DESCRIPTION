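Package: fervote
Title: Rater-Group and Mask-Condition Analysis of Facial Expression Vote Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how categorical facial-expression labels vary
    across rater groups and face-masking conditions. Implements the three
    encodings of crowd-sourced emotion votes (vote counts, one-hot majority
    with deterministic tie-breaking, and vote rates), confusion-matrix
    agreement statistics (precision, binary and multiclass Cohen's kappa,
    cell-wise Fisher exact tests with false-discovery-rate control),
    cross-group vote-rate difference and category shift maps, per-emotion
    correlation comparisons via the Fisher r-to-z transform, Tukey-Kramer
    multiple comparisons, landmark-based synthesis of masked face stimuli,
    and the eye-opening-rate statistic computed from 68-point facial
    landmarks. A synthetic rater-panel and landmark generator reproduces the
    statistical structure of a two-group (17 + 10 rater), two-condition,
    98-face forced-choice study so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
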