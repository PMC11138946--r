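Package: bseir
Title: Behavior-Coupled SEIR Epidemic Dynamics with Delayed Risk Information
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a two-group SEIR-type epidemic model in which the
    proportion of susceptibles engaging in prophylactic behavior (e.g. mask
    wearing) is a generalized-logistic function of delayed risk information:
    perceived prevalence of detected cases and the relative trend in new
    detected cases, modulated by in-group pressure.  The coupled system is a
    neutral delay differential system solved with deSolve.  Includes an
    epidemic wave detector based on peak prominence and trough rules,
    epidemic severity measures (wave count, peak height and time, time to
    curb, final size), a deterministic simulation-experiment grid over
    transmission, detection, delay, protection and in-group parameters, and
    summary regressions (Poisson, gamma, and one-inflated beta) for the
    resulting severity measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
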