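Package: aspirindm
Title: Markov Cohort Cost-Effectiveness Model of Low-Dose Aspirin for
    Primary Cardiovascular Prevention in Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A five-state Markov cohort model comparing daily low-dose
    aspirin with no aspirin for primary prevention of cardiovascular
    disease in 60-year-old Chinese patients with type 2 diabetes.
    Implements the decision-analytic engine (yearly cycles, tunnel states
    for first-year post-event mortality, 3% discounting), trial-based
    validation of simulated event rates, one-way and threshold sensitivity
    analyses, scenario analyses, and a full probabilistic sensitivity
    analysis with beta/lognormal/uniform parameter distributions,
    cost-effectiveness acceptability curves, and expected value of perfect
    information. An individual-level microsimulation of the same transition
    rules is included as an internal cross-check of the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
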