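Package: diastolefit
Title: Passive Myocardial Stiffness and Diastolic Residual Active Tension
    Estimation for the Left Ventricle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint estimation of passive myocardial constitutive parameters
    (reformulated Guccione law), the unloaded reference configuration, and the
    residual diastolic active tension profile of the left ventricle from a time
    series of diastolic shapes and cavity pressures.  Provides a reduced-order
    incompressible forward inflation model on an idealized axisymmetric
    thick-walled ventricle with transmurally rotating fibers, the backward
    (deflation) operator, least-squares propagation of tensor-product
    cubic-Hermite meshes to tracked material points, a sweep-based estimation
    algorithm with an active-tension criterion for reference-frame selection,
    and an in silico validation harness with a six-scenario sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    generics,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
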