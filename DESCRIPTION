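Package: photokin
Title: Photophysics and Voltage-Sensing Analyses for Microbial Rhodopsin
    Fluorescence Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global kinetic analysis of femtosecond-to-microsecond transient
    absorption spectra (IRF-convolved sequential and branched compartment
    models fitted by variable projection, yielding evolution-associated
    difference spectra and photoproduct branch yields), reconvolution fitting
    of fluorescence decay histograms with fractional-amplitude and mean
    lifetime summaries, steady-state photophysics calculations (Nernst
    membrane-voltage calibration, relative fluorescence quantum yield,
    Schiff-base pKa titration fitting, HPLC isomer-fraction integration,
    Stern-Volmer quenching), and hydrogen-bond-network and side-chain
    orientation analysis of molecular dynamics trajectories. Includes
    generators that simulate every input type with known ground truth so the
    complete pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    bio3d,
    jsonlite
Config/testthat/edition: 3
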