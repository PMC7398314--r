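Package: pmrtcea
Title: Cost-Effectiveness Modelling of Post-Mastectomy Radiotherapy
    Techniques
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Markov cohort model for the cost-effectiveness of
    post-mastectomy radiotherapy (PMRT) techniques in breast cancer,
    including late radiogenic side effects (cardiac toxicity,
    contralateral breast cancer, lung cancer). Propagates a hypothetical
    cohort through annual health-state transitions over a 15-year
    horizon, accumulates discounted costs and quality-adjusted
    life-years, ranks strategies on the cost-effectiveness frontier with
    dominance flags and incremental cost-effectiveness ratios, and
    quantifies uncertainty with one-way (tornado) sensitivity analysis
    and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. Ships a human-editable YAML parameter format,
    a bundled reference parameter set for a 55-year-old PMRT cohort, and
    generators for synthetic and degenerate parameter sets with
    closed-form outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
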