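Package: soilqual
Title: Soil Quality Index and Ecosystem Multifunctionality Analysis for
    Amendment Field Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing randomized field trials of saline-soil
    organic amendments. Provides a calibrated synthetic-trial generator,
    directional min-max scoring of soil properties with the radar-area
    soil quality index (SQI), Z-score ecosystem multifunctionality (EMF)
    from extracellular enzyme activities, one-way ANOVA with Fisher's
    LSD compact letter displays and percent-change reporting, pairwise
    correlation panels, linear regressions among SQI, EMF and yield, and
    random-forest permutation importance of yield drivers, orchestrated
    into a reproducible seeded pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
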