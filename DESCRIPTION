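Package: muactarget
Title: Targeting Consequences of Expanded MUAC-Only Acute Malnutrition Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how an "expanded MUAC-only" admission policy
    (mid-upper arm circumference < 125 mm or nutritional oedema as the sole
    anthropometric entry criterion) would re-target children identified as
    acutely malnourished by current WHO case definitions. Computes
    weight-for-height z-scores from sex-specific LMS growth-reference tables
    with the WHO restricted adjustment and flagging rules, applies SAM/MAM/GAM
    case definitions by MUAC and WHZ, assigns each case to a mutually exclusive
    targeting scenario category (excluded, underestimated, ignored-risk or
    correctly detected SAM; excluded or included MAM), aggregates counts across
    surveys, countries and regions before forming proportions, and derives
    program metrics including the ready-to-use therapeutic food (RUTF)
    allocation-increase ratio. A two-stage cluster-survey simulator with a
    controllable joint distribution of WHZ and MUAC deficits, plus an analytic
    bivariate-normal oracle for expected category probabilities, supports
    end-to-end testing where child-level survey microdata are restricted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
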