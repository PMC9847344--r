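Package: vibralign
Title: Alignment and Scoring of Vibrational Spectra for Stereoisomer Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare theoretical and experimental vibrational spectra
    (IR, Raman, VCD) for the assignment of relative and absolute stereochemistry.
    Continuous spectra are deconvoluted into pseudo-Voigt bands by simultaneous
    bounded least squares; the resulting peak lists are aligned by global dynamic
    programming under a smooth, compactly supported (mollifier) scoring function,
    optionally across several spectroscopies at once. Conformer line spectra are
    Boltzmann-weighted and broadened; candidate stereoisomers are ranked with
    alignment scores, Pearson and Spearman correlations of the aligned spectra,
    a combined score, and a screening over harmonic frequency scaling factors.
    Includes a synthetic fixture generator and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
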