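Package: htpbpk
Title: Bottom-Up Rat PBPK Simulation and IVIVE Prediction Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for bottom-up physiologically based pharmacokinetic (PBPK)
    prediction of rat pharmacokinetics in an early drug-discovery setting.
    Implements in vitro-in vivo extrapolation (IVIVE) of hepatic clearance
    from suspended-hepatocyte intrinsic clearance under four incubation
    binding assumptions plus back-calculation from observed plasma clearance
    via the reverse well-stirred model; mechanistic tissue partitioning and
    steady-state volume of distribution (Rodgers-Rowland with a logD-based
    lipid term); an 11-tissue whole-body rat PBPK model and a reduced
    single-compartment high-throughput variant; a compartmental
    absorption-and-transit oral model with pH- and bile-salt-dependent
    solubility and particle dissolution; noncompartmental analysis; the
    standard fold-error prediction-success metric panel; a synthetic compound
    library generator emulating early-discovery property distributions; and a
    batch evaluation pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
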