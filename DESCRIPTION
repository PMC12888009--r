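Package: venomtools
Title: Quantitative Snake Venomics, Third-Generation Antivenomics and
    Antivenom Potency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative snake venomics and antivenom
    characterization. Converts reversed-phase chromatographic peak areas
    into toxin-family mass and molar abundances, computes molar ratios
    and compositional-pattern classifications for Bothrops venoms,
    quantifies third-generation antivenomics (immunoaffinity) binding
    including saturation extrapolation and maximal binding capacity,
    estimates LD50/ED50 by probit regression with delta-method
    confidence intervals, and carries the potency, neutralizing-antibody
    and vials-per-bite dosing algebra. A synthetic-data generator
    produces chromatograms, immunocapture series and dose-response
    tables with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
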