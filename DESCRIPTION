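Package: actionreg
Title: Neurodynamical Simulation of Action Regulation and Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulator of a neurodynamical theory of action
    regulation in which dynamic neural fields (local excitation, surround
    inhibition) compete to plan reaching movements, a basal-ganglia-style
    "pause" field inhibits the reach planning field, and movements are
    generated by a mixture of finite-horizon optimal feedback controllers
    under receding-horizon re-planning.  Implements three behavioral
    protocols (free-choice decision, arrow flanker, stop-signal with a
    1-up/1-down stop-signal-delay staircase) under neurotypical and
    Parkinson's-disease parameterizations, trajectory-based behavioral
    metrics (spline-smoothed velocity reaction times, exclusion rules,
    change-of-mind detection, stop psychometrics) and the group-level
    statistics used to compare the parameterizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
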