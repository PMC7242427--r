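Package: memswell
Title: Osmotic Swelling of Closed Membranes with Stretching and Bending
    Mechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates osmotic swelling of closed-membrane systems
    (erythrocyte-like oblate axisymmetric ellipsoids) by coupling osmotic
    pressure, a deformation-dependent membrane rigidity tensor with
    disruption at large strain, and water-flux volume dynamics.  Includes
    exact spheroid differential geometry with spectral surface quadrature,
    a linearized analytic swelling model, the classical osmotic-only
    baseline, and an inverse Helfrich solver that recovers the
    bending-induced pressure and surface tension of a prescribed
    equilibrium shape from the Euler-Lagrange shape equation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
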