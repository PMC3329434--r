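Package: rotumble
Title: Rotational-Diffusion Analysis of Bacterial Run-and-Tumble Motility
Version: 0.1.0
Authors@R: person("rotumble", "authors", email = "rotumble@example.org",
    role = c("aut", "cre"))
Description: Models the tumbles of swimming bacteria such as Escherichia coli
    as an active rotational diffusion process. Provides the Legendre-polynomial
    propagator of orientation on the sphere, directional autocorrelation
    functions in three dimensions and in the microscope observation plane,
    tumble-time-marginalized reorientation distributions and their
    maximum-likelihood fitting, a Monte-Carlo random walk on the sphere, a
    synthetic run-and-tumble trajectory generator (homogeneous media, shallow
    chemoattractant gradients, and propagating-wave regimes with
    direction-dependent reorientation), trajectory segmentation into runs and
    tumbles, per-quadrant correlation analysis, rotational-diffusion
    coefficient estimators with bootstrap uncertainties, and chemotactic drift
    and persistence metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
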