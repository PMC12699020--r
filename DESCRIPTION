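Package: cahscreen
Title: Second-Tier Newborn Screening Algorithms for Salt-Wasting
    Congenital Adrenal Hyperplasia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for developing and evaluating second-tier dried-blood-spot
    steroid-profile screening algorithms for salt-wasting 21-hydroxylase
    deficiency congenital adrenal hyperplasia (SW-CAH). Provides a seeded
    synthetic cohort generator emulating a tier-1-positive screening
    population with limit-of-detection-censored 21-deoxycortisol, the
    three-component decision rule (detectable 21-deoxycortisol,
    17-hydroxyprogesterone + 21-deoxycortisol sum, steroid ratio to
    cortisol), legacy and single-analyte comparator rules, screening
    performance metrics with gestational-age stratification, a Monte Carlo
    threshold search under a sensitivity constraint, and principal components
    exploration of the steroid panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
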