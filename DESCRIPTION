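Package: storekin
Title: Storage-Stability Kinetics of Carotenoid Degradation in Beverages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the degradation of carotenoid pigments in
    coloured beverages during dark and illuminated storage. Fits zero-order,
    first-order and fractional-conversion kinetic laws jointly across storage
    temperatures by one-step nonlinear regression with the rate constant
    substituted by the Arrhenius relation, so the reference rate constant and
    activation energy are estimated directly. Provides F-based joint
    confidence regions for the rate parameters, conversion between cumulative
    light dose (megalux-hours) and equivalent retail shelf days, Welch-type
    comparison of rate constants with and without added ascorbic acid,
    ascorbic-acid/oxygen stoichiometry accounting, and a synthetic-data
    generator that emulates a multi-temperature storage study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
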