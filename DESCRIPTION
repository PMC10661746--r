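Package: quantiso
Title: Isobolographic Analysis of Quantal Dose-Response Drug Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantal (all-or-none) dose-response bioassay and
    fixed-dose isobolographic analysis of drug mixtures. Fits log-probit
    dose-response curves by maximum likelihood to obtain median effective
    doses (ED50) with delta-method standard errors, transforms fixed-dose
    two- and three-drug mixtures onto the ED50-fraction scale under Loewe
    additivity, computes theoretical additive and experimental mixture ED50s,
    per-drug dose fractions and the fraction (interaction) index, classifies
    interactions as synergistic, additive or antagonistic with Welch's
    unequal-variance t-test (integer Satterthwaite degrees of freedom), and
    provides Dunnett-style many-to-one comparisons of potency estimates.
    Includes a synthetic quantal-data generator with known ground truth so
    the whole pipeline is testable end-to-end, and a study driver that
    reproduces publication-style interaction tables from either raw quantal
    counts or printed summary estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
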