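Package: duplexmelt
Title: Thermodynamic Analysis of DNA Duplex UV Melting Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-state van't Hoff analysis of UV melting curves of short DNA
    duplexes: nonlinear least-squares fitting of absorbance transitions on
    sloping linear baselines, Tm(-1) versus log(Ct/4) concentration-dependence
    regression, nearest-neighbor stability prediction including internal G.T
    wobble pairs and trinucleotide-core decomposition, and salt-dependence
    analysis converting d(-dG)/dlog[M] slopes into counterion-uptake numbers
    for Na+ and Mg2+ solutions.  Includes a seedable synthetic melting-curve
    generator for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
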