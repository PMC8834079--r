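Package: ojipsuite
Title: JIP-Test and Multi-Signal Chlorophyll Fluorescence Kinetics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of simultaneously recorded prompt chlorophyll a
    fluorescence (OJIP transients), modulated 820 nm reflection (P700 and
    plastocyanin redox kinetics), and delayed chlorophyll fluorescence
    induction curves from plant-efficiency-analyzer style instruments.
    Extracts OJIP fiducial markers and computes the JIP-test energy-flux
    parameter set (quantum yields, efficiencies, per-reaction-center and
    per-cross-section fluxes), derives PSI oxidation and re-reduction slope
    parameters from MR/MRo kinetics, extracts delayed-fluorescence induction
    features and decay constants, quantifies chlorophylls and carotenoids by
    the Lichtenthaler equations, and compares experimental groups with
    one-way ANOVA and Fisher's least-significant-difference test. Includes
    a synthetic-signal generator with known ground truth so every analysis
    stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    rlang,
    signal,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
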