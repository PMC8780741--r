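Package: preformr
Title: Biopharmaceutical Preformulation: pKa, Solubility-pH Speciation,
    Permeability and Provisional BCS Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for early-stage biopharmaceutical
    characterization of drug candidates. Estimates dissociation constants
    from absorbance-pH spectra by the crossing-point method; models the
    solubility-pH profile of an ordinary ampholyte with optional
    hydrochloride-salt precipitation and common-ion effect, simulates a
    full-range titration with self-consistent ionic-strength and
    activity-coefficient (Davies) corrections, and refines intrinsic
    solubility and the salt solubility product by weighted nonlinear least
    squares; fits apparent permeability from non-sink transwell transport
    data with periodic sample replacement and effective intestinal
    permeability from closed-loop (Doluisio) perfusion time courses; and
    combines dose number with reference-compound permeability comparisons
    into a provisional Biopharmaceutics Classification System (BCS) class.
    Seeded synthetic-data generators with embedded ground truth make the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
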