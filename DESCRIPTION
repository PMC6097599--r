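Package: thermoresp
Title: Flow-Through Respirometry Processing and Thermal Physiology of Endotherms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes flow-through respirometry chamber traces into standard
    thermal, metabolic and hygric physiological variables for endotherms, and
    compares populations. Includes instrument calibration, baseline drift
    correction, dry-nitrogen mass-balance inversion to oxygen consumption and
    carbon dioxide production, psychrometric evaporative water loss,
    steady-and-minimal analysis window detection, derivation of respiratory
    exchange ratio, metabolic heat and water production, evaporative heat
    loss, wet and dry thermal conductance, relative water economy and its
    crossing point, allometric mass correction, quadratic thermal-response
    mixed models with individual random intercepts, and one-way ANOVA with
    Student-Newman-Keuls groupings. A physiologically structured synthetic
    trace generator (Scholander-Irving steady state with first-order chamber
    washout, analyzer noise and drift) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
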