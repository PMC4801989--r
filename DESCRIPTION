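Package: pepkit
Title: Peptide and Peptoid Property Calculation and Mass Spectral Peak
    Assignment
Version: 0.1.0
Authors@R:
    person("Sam", "Ward", email = "sam.ward@example.org", role = c("aut", "cre"))
Description: Offline calculators for synthetic peptide and peptoid
    chemistry: molecular formula and monoisotopic (most-abundant-isotope)
    molecular weight, isoelectric point by bisection on the
    Henderson-Hasselbalch net-charge equation, molar extinction
    coefficients at 280 nm, residue charge summaries, and beta-strand
    contiguity profiles from Chou-Fasman propensities (the SALSA sliding
    window method).  Includes an iterative-deepening engine that assigns
    singly-charged m/z peaks from synthesis mass spectra to residue
    deletion sequences, metal adducts and unremoved protecting groups,
    plus ChemDraw CDXML structure export and a command-line front end.
    Residue, terminus, protecting-group, pKa and propensity tables ship
    as editable plain-text data files and can be extended at run time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
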