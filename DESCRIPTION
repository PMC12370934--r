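Package: gpkin
Title: Model Catalogue, Fitting and Selection for In Vitro Gas Production Kinetics
Version: 0.1.0
Authors@R: person("gpkin", "maintainers", email = "gpkin@example.org", role = c("aut", "cre"))
Description: Tools for modelling cumulative in vitro gas production (GP)
    measured with the Hohenheim Gas Test. Provides a fixed catalogue of 21
    phenomenological growth models built from scaled cumulative distribution
    functions, with analytic inflection times and half-lives; constrained
    nonlinear least-squares fitting with BIC-centred goodness-of-fit metrics
    and a failure taxonomy; a selection layer combining factorial ANOVA with
    Tukey HSD groupings, a regression-tree partition of model-by-feed
    performance, and relative performance improvement (RPI) statistics; and a
    seeded synthetic-data generator that emulates the assay's sampling design
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
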