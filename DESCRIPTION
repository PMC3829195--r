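Package: vsdcontext
Title: Contextual Modulation Analysis for Voltage-Sensitive Dye Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mesoscopic voltage-sensitive dye imaging
    (VSDI) studies of long-range contextual interactions in visual cortex.
    Implements the two-step delta-F/F preprocessing (divisive prestimulus
    normalization followed by blank subtraction and blank normalization),
    constrained fitting of spatial activity profiles with a superposition of
    two rotated two-dimensional Gaussians, derivation of the four
    characteristic activation types (direct, indirect, coherent, incoherent),
    facilitation, superadditivity and coherence-specificity indices with
    bootstrap confidence intervals and nonparametric tests, and
    percentile-ROI time-course and cross-location correlation analysis.
    Includes a synthetic trial-stack generator with exported ground truth
    (two Gaussian cortical spots driven by correlated temporal signals,
    paired-condition facilitation, heartbeat-like artifacts shared with
    blank trials) for end-to-end parameter-recovery testing, and a reader
    for the deposited EVO-format evoked datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
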