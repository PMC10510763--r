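Package: drlkin
Title: Delayed Reactant Labelling Kinetics from Time-Resolved Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies ligand-exchange kinetics of metal complexes from
    electrospray-ionization mass spectrometry (ESI-MS) isotopologue time
    traces acquired with the delayed reactant labelling (DRL) protocol.
    Provides a mechanistic simulator of the single-site and two-site
    exchange schemes, extraction and normalization of relative-intensity
    observables from peak-list series (including isotope-envelope overlap
    correction and bis-complex renormalization), global pseudo-first-order
    fitting of dissociation rate constants with uncertainty and
    quantitation-limit diagnostics, Eyring analysis yielding activation
    parameters, and a seeded synthetic-data generator for end-to-end
    validation without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
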