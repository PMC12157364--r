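Package: tcndyn
Title: Transposon Copy Number Dynamics Under Fluctuating Antibiotic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained population model of transposon-plasmid nesting in
    bacteria. A population is partitioned into subpopulations by transposon
    copy number (TCN); transposition and plasmid copy number dynamics move
    cells between adjacent TCN classes while logistic growth, Hill-type
    antibiotic inhibition and dilution shape subpopulation sizes. The package
    integrates the resulting ODE system under fixed and fluctuating
    antibiotic protocols, computes gain/loss response rates for simulated and
    serial-passage experimental time series, implements standard-curve qPCR
    copy-number arithmetic (amplification factor, primer efficiency, relative
    PCN/TCN per genome), and generates synthetic 21-day serial-passage
    datasets (OD600, GFP/OD, Ct tables) so the whole analysis pipeline can be
    validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
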