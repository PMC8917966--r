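Package: ecpump
Title: Flowrate Modelling for Electrochemically Actuated Drug-Delivery Micropumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the drug-delivery flowrate of implantable bioelectronic
    micropumps actuated by water electrolysis. The gas generated by the
    electrochemical reaction inflates a flexible membrane that pumps drug
    through a rectangular microchannel; the process is governed by a
    first-order ordinary differential equation derived from the ideal gas
    law. The package nondimensionalizes the problem into three groups
    (initial pressure, initial gas volume, microfluidic resistance),
    integrates the governing equation numerically, provides the matched
    slow/fast singular-perturbation solution that enforces the
    zero-initial-flowrate condition, and evaluates an explicit closed-form
    formula for the maximum flowrate used to screen designs against
    published safe-flowrate ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
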