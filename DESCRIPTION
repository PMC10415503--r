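Package: suturemorph
Title: Geometric Morphometrics and Spectral Complexity Scoring of Suture Outlines
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end analysis of two-dimensional cranial suture outlines,
    built for the midpalatal suture. Provides fixed-count equidistant
    semi-landmark resampling with Procrustes-distance sliding, generalised
    Procrustes superimposition, principal component morphospaces, a windowed
    short-time Fourier transform power-spectral-density (PSD) interdigitation
    complexity score, and the accompanying statistical battery (Shapiro-Wilk
    gate, factorial ANOVA, Holm-corrected pairwise t tests, intraclass
    correlation for repeated digitisations). Includes a parametric generator
    of synthetic suture cohorts with known ground-truth morphology, plus
    readers and writers for delimited coordinate tables and TPS landmark
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
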