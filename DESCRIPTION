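Package: crccsim
Title: Hybrid ODE Modelling of Trastuzumab-Induced Cognitive Side Effects
    and Combination Dosing Schedules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a hybrid ordinary-differential-equation model of
    cancer-related cognitive changes ("chemo-brain") arising during long-term
    trastuzumab therapy and their rescue by adjuvant atorvastatin. The model
    couples an intracellular apoptosis-switch network (NF-kB, Bcl-2, BAX)
    driven by IL-6 to tumor and cancer-stem-cell dynamics, with
    indicator-function switching of tumor-cell killing. Provides closed-form
    intracellular equilibria and local stability, therapy protocols (clamped
    levels, periodic infusions, alternating six-slot schedules),
    event-resolved simulation, efficacy and phase-plane response analysis,
    infusion-schedule scans and exhaustive schedule ranking, Latin-hypercube
    sampling with partial-rank-correlation sensitivity analysis, and a
    synthetic-observation generator with multi-start parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
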