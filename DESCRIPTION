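Package: ecodebt
Title: Agent-Based Simulation of Debt-Driven Economies Coupled to a
    Renewable Resource Landscape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless agent-based simulator of a monetary-circuit,
    debt-based economy (firms, households, a commercial bank, credit-funded
    speculators) coupled to a spatial grid of renewable biomass patches.
    Implements fractional-reserve versus full-reserve banking scenarios,
    threshold-triggered government conservation policies
    (technology-investment caps, speculation limits, protected-area
    expansion, land restoration), seeded replicate ensembles with
    standard-error bands, one-factor-at-a-time sensitivity sweeps, and
    resource-collapse detection, with stock-flow-consistent money and
    biomass accounting audited at every tick.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
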