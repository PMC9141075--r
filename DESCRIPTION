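Package: nurseflex
Title: Coherence-Based Nurse Planning for Multi-Unit Care Systems
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Shift-level planning and what-if simulation of nurse flexibility
    strategies in an interdependent multi-unit (perinatology) care system.
    Provides a Markov one-shift-ahead census and demand predictor, three
    centralized reallocation strategies (skill-based reallocation, a
    centralized float pool, and their combination), a seeded stochastic
    demand generator calibrated to a target coefficient of variation, a
    scenario runner for alternative care-system configurations, and a
    decision layer (under-/overstaffing summaries, best-strategy selection,
    decision regret, training cost, flexible-nurse and flexible-bed sizing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
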