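Package: sipcop
Title: Seat Interface Pressure and Seated Centre of Pressure Analysis for
    Wheelchair Pressure Redistribution Manoeuvres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and estimation tools for relating seat interface pressure
    (SIP) under the ischial tuberosities to the seated centre of pressure
    (CoP) while wheelchair users perform leaning pressure-redistribution
    manoeuvres. Implements a three-segment rigid-body lean model with
    closed-form CoP magnitudes, a uniform-elasticity beam model of the
    interface pressure profile with per-individual theoretical SIP-CoP
    slopes, a deterministic synthetic trial simulator (corner load cells,
    pressure mat, inertial measurement units), the multirate processing
    pipeline (taring, nearest-timestamp alignment, ischial region selection,
    max-pressure normalization, truncation, per-condition regression, sine
    fits, offloading thresholds, Bland-Altman agreement), and linear
    mixed-effects modelling of direction and cushion effects with AIC/BIC
    structure comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
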