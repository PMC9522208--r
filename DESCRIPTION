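Package: spirascale
Title: Allometric Scaling and Gas-Exchange Capacity of Insect Spiracles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the allometric scaling of insect spiracles
    and its consequences for respiratory gas exchange. From per-spiracle
    morphometric measurements (two orthogonal opening diameters and a depth)
    the package computes elliptical opening areas, Fick's-law diffusive
    conductances and Poiseuille advective conductances, the oxygen
    partial-pressure gradient required to supply resting or flight metabolism
    by diffusion, and log-log scaling fits of every metric against body mass
    with nonparametric bootstrap confidence intervals and p-values, Bayesian
    linear regression, and phylogenetic generalized least squares with
    Pagel's lambda, including a lambda-identifiability profile diagnostic.
    A synthetic-data generator produces measurement tables and trees with
    the statistical structure the analysis assumes, for testing and
    calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    coda,
    rjags,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
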