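Package: harvestMSE
Title: Management Strategy Evaluation for Wildlife Harvest Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-complex Management Strategy Evaluation (MSE) framework for
    terrestrial wildlife harvest. Simulates closed-loop harvest systems
    coupling stochastic logistic population dynamics, imperfect monitoring,
    quota setting under stakeholder influence, and imperfect harvest
    implementation, across factorial combinations of species life histories,
    variability levels, and starting-population scenarios. Evaluates
    sustainability with ten individual metrics standardized to a 0-100 scale
    and aggregated into six composite stakeholder perspectives, and provides
    a comparative decision-analysis layer: optimal harvest parameters and
    strategies per context, pairwise context contrasts, value forgone, and
    the information value of knowing the environmental or evaluation context.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
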