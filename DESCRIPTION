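Package: inhibisense
Title: Bacterial Inhibition Biosensor Array Analysis with Neural-Network
    Pollutant Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a whole-cell electrochemical inhibition
    biosensor array in which three immobilized bacterial channels (Escherichia
    coli, Methylococcus capsulatus, Shewanella oneidensis) respond to twelve
    water pollutants. Simulates cyclic voltammograms and electrochemical
    impedance spectra of the sensing electrodes, extracts the normalized
    anodic-current inhibition response and equivalent-circuit parameters,
    screens samples into heavy-metal, pesticide and petrochemical groups, and
    identifies pollutant identity plus quantized concentration with a
    3-12-6 multilayer perceptron trained by the Levenberg-Marquardt
    algorithm against a 6-bit class codebook.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
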