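Package: qpcrmix
Title: Joint Mixed-Model Relative Quantification of qPCR Expression and
    Adipose Fatty-Acid Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Efficiency-adjusted relative quantification of qPCR gene
    expression by a joint linear mixed model on -log2-transformed Cp values,
    with contrast-based fold changes, asymmetric confidence intervals,
    reference-gene stability selection (geNorm and NormFinder style), and
    Benjamini-Hochberg multiple-testing correction using the effective number
    of tests.  Includes fatty-acid composition indices (SFA, MUFA, PUFA,
    n-6/n-3) and breed-by-diet mixed models for adipose tissue profiles, plus
    simulators that emulate a two-breed (Iberian/Duroc), two-diet feeding
    trial with fasting and postprandial biopsies for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    Matrix,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
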