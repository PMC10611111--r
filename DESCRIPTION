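Package: gaitcoord
Title: Instrumented Gait Analysis and Coordination-Phenotype Classification
        from Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("UMCG", "Movement Analysis", email = "gaitcoord@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for instrumented gait and tandem-gait analysis
    from tri-axial inertial measurement units (IMUs) worn on the shanks,
    thighs and trunk. Segments gait cycles from shank mediolateral angular
    velocity (mid-swing peak, toe-off and heel-strike valleys), extracts a
    36-feature catalogue of temporal, spatial, angular-range, variability and
    smoothness characteristics (including dynamic-time-warping distance to
    the participant mean cycle and hip flexion-extension range), and
    classifies participants into three coordination phenotypes (early onset
    ataxia, developmental coordination disorder, typically developing
    controls) with a leave-one-participant-out, ADASYN-balanced random-forest
    protocol with majority voting. A synthetic multi-sensor cohort generator
    with known ground-truth events makes every stage testable without
    patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    FNN,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
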