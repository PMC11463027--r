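Package: cspselect
Title: Electrode Selection for Motor-Imagery EEG with Common Spatial Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-class motor-imagery EEG classification and
    electrode selection. Implements a common spatial patterns (CSP) plus
    linear discriminant classification pipeline with stratified
    cross-validation, exhaustive electrode-subset search with one-sided
    t-test selection across subjects, a CSP-pattern threshold
    electrode-extraction algorithm, beta-binomial Bayesian A/B evaluation
    of pipeline variants by Monte-Carlo ratio sampling, and a synthetic
    EEG session generator with a known band-power contrast for
    ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
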