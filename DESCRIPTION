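Package: eq5dcua
Title: EQ-5D Scoring-Method Comparison for Trial-Based Cost-Utility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-arm trial-based economic-evaluation data with a
    controlled EQ-5D health-state structure, scores the simulated health
    states under country-specific value sets (tariffs) and version
    crosswalks (5L to 3L and 3L to 5L), runs full cost-utility analyses
    (area-under-the-curve QALYs, seemingly unrelated regression,
    bias-corrected and accelerated bootstrap, cost-effectiveness
    acceptability curves), and quantifies how the choice of scoring method
    changes utilities, QALYs, ICERs, and probabilities of
    cost-effectiveness across a factorial of health conditions, severity
    levels, and treatment effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
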