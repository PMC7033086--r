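Package: fbpakin
Title: Kinetic Modeling of 18F-FBPA PET for Tissue Boron Estimation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the total distribution volume (Vt) of the reversible
    PET tracer 4-borono-2-[18F]-fluoro-L-phenylalanine (18F-FBPA) in normal
    organs from dynamic whole-body time-activity curves, using the Logan
    graphical plot and the Ichise multilinear analyses MA1 and MA2 with
    automatic equilibration-time (t*) selection.  Includes
    metabolite-corrected bi-exponential modeling of the arterial plasma
    input function, goodness-of-fit model comparison (AIC, reduced
    chi-square, Sy.x, R squared), a two-tissue-compartment study simulator
    on the 7-frame whole-body schedule, and conversion of Vt plus plasma
    activity into tissue boron-10 concentration (ppm) for boron neutron
    capture therapy dosing with 10B-BPA-fructose.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, minpack.lm, jsonlite
Suggests: testthat (>= 3.0.0), deSolve, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
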