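Package: fishtpa
Title: Texture Profile Analysis of Fish Fillets with Thickness
    Residualization and Sensory Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for instrumental texture profile analysis (TPA) of fish
    fillets from double-compression force-time curves: a seeded simulator of
    two-cycle compression traces and whole cohorts with linked sensory
    panels, anchor-point detection and trapezoidal work integration,
    computation of the standard and extended TPA attributes (hardness,
    cohesiveness, springiness, resilience, adhesiveness, chewiness,
    thickness), removal of the fillet-thickness contribution by
    linear-regression residualization, per-fish aggregation with two-group
    comparison of processing treatments, and prediction of descriptive
    sensory texture attributes from TPA attributes via published equations
    or forward stepwise regression with squared and cross-product terms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
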