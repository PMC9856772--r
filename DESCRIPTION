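Package: dfucea
Title: Markov Cohort Cost-Effectiveness Modelling of Diabetic Foot Ulcer Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic modelling of adjunct wound-care strategies for
    diabetic foot ulcers. Implements a six-state monthly Markov state-transition
    model (healed, uninfected ulcer, infected ulcer, gangrene, post-amputation,
    death) with odds-ratio treatment-effect adjustment, deterministic cohort
    simulation with discounted cost, life-year and QALY accumulation,
    individual-level microsimulation for clinical event counting, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, one-way
    (tornado) and two-way deterministic sensitivity analyses, break-even
    drug-cost search, scenario analysis, and a structural calibration harness
    for ambiguous published transition inputs. Model definitions are plain YAML
    files; a calibrated parameterization of a published ON101 wound-care
    evaluation is shipped as the default model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
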