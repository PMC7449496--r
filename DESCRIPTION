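Package: iksvar
Title: In-Silico Risk Stratification of KCNQ1 (IKs) Channel Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Hodgkin-Huxley models of the slow delayed-rectifier
    potassium current (IKs) to patch-clamp summary statistics of KCNQ1
    variants (shift in half-activation voltage, change in activation slope,
    and fractional current density), propagates each fitted variant through
    a phenotypically variable population of spontaneously beating induced
    pluripotent stem-cell derived cardiomyocyte (iPSC-CM) models under a
    physiological noise-current protocol, and classifies each variant's
    long-QT severity from the fraction of model cells crossing three
    proarrhythmia criteria (increases in action-potential triangulation,
    beat-to-beat variability of APD90, and APD90 prolongation). Fitted
    variants can additionally be translated into a paced adult ventricular
    myocyte model via conductance rescaling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
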