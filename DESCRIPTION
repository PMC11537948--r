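Package: bcref
Title: Body-Composition Reference Curves by BCCG (LMS) Penalized GAMLSS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construction and use of age- and sex-specific reference values for
    pediatric body composition (fat-mass index, fat-free-mass index) estimated
    by skinfold anthropometry, multifrequency bioimpedance and DXA.  Implements
    the Box-Cox-Cole-Green (LMS) distribution, penalized P-spline GAMLSS
    fitting of age-varying L/M/S curves with GCV-selected smoothness,
    metabolic-health eligibility screening, centile-table generation, z-score
    scoring against published LMS tables, and a synthetic-cohort generator for
    end-to-end testing and parameter-recovery experiments.  Ships published LMS
    reference tables for urban Mexican children and adolescents aged 5-18
    years as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
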