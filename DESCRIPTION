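Package: sijstrain
Title: Sacroiliac Joint Ligament Strain Simulation and Lesion Statistics
    for the Canine Pelvis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale rigid-body re-formulation of a finite-element model
    of canine sacroiliac joint ligament strain. Provides a parametric,
    Labrador-scale synthetic pelvis (landmarks, CT-like phantom with
    threshold segmentation), nonlinear tension-only ligament spring
    networks, a compression-only hyperelastic sacrocaudal joint with a
    three-parameter Mooney-Rivlin fit, static equilibrium by potential
    energy minimization, an eight-scenario load battery with per-ligament
    strain averaging, an intra-observer repeatability study based on
    per-cell regression slopes, and lesion-count cohort statistics
    (one-way ANOVA, Fisher's protected LSD, factorial ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
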