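Package: fiberpol
Title: Polarized-Fluorescence Order Parameters and Calcium Titration
    Analysis for Striated Muscle
Version: 0.1.0
Authors@R:
    person("Fiberpol", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing polarized fluorescence measurements from
    oriented fluorescent probes in permeabilized muscle preparations. Provides
    a forward and inverse optical model linking probe orientation
    distributions to the four polarized fluorescence intensity components and
    the Legendre order parameters <P2> and <P4>; a free-calcium solver for
    mixed Ca/Mg/EGTA/ATP bathing solutions; Hill-equation fitting of
    force-pCa and <P2>-pCa titrations; paired-design summary statistics with
    significance flags; and a deterministic synthetic-data generator that
    emulates sarcomere length and force-inhibitor experimental designs for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
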