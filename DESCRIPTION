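Package: mesiso
Title: Quantal Dose-Response and Fixed-Dose Isobolographic Analysis of
    Antiseizure Drug Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing quantal (protected/not protected)
    dose-response experiments of the maximal electroshock seizure (MES)
    type and for classifying fixed-dose add-on drug combinations as
    additive or synergistic by isobolographic transformation. Implements
    maximum-likelihood log-probit estimation of the median effective dose
    (ED50) with delta-method confidence limits, conversion between
    confidence limits and standard errors, probit-window animal counting,
    theoretical additive mixture ED50s with delta-method variance
    propagation, Welch-type comparison of experimental and additive
    mixture potencies, summary-statistics one-way ANOVA with Tukey-Kramer
    and Dunnett post-hoc procedures, analysis of total brain drug
    concentration groups, polygonogram and isobologram displays, and a
    synthetic-data generator that emulates the MES experimental design
    with a controllable departure from dose-additivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
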