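Package: mavtkit
Title: Multi-Attribute Value Theory with MACBETH Elicitation for Health
    Technology Appraisal
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates additive multi-attribute value models of
    the kind used in facilitated health technology appraisal workshops.
    Converts qualitative pairwise difference-of-attractiveness judgments
    into cardinal value scales by linear programming (the MACBETH
    approach), constructs reference-level anchored piecewise-linear value
    functions, derives normalized criteria weights from qualitative swing
    comparisons, aggregates weighted partial value scores into overall
    preference values with rankings and contribution decompositions,
    computes one-way weight sensitivity (rank-reversal) thresholds and
    robustness margins, and performs cost-per-value-unit and dominance
    analysis on the value-cost plane.  Ships a fully worked metastatic
    colorectal cancer appraisal of three second-line biological
    treatments, plus a generator of random decision problems for testing
    every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    quadprog,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
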