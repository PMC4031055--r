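Package: hippomorph
Title: Attractor Dynamics in a Spiking Model of the Hippocampal EC/DG/CA3 Circuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates gamma-cycle winner-take-all spiking of dentate gyrus and
    CA3 populations driven by medial entorhinal grid cells and lateral
    entorhinal morph-sensitive cells, builds and updates Hebbian recurrent CA3
    "memory" weights from activity in two reference environments, and runs
    environment-morphing experiments (square to circle) with the standard
    remapping analyses: occupancy-normalized rate maps, place-field detection,
    population-vector correlation and autocorrelation, rate overlap, and
    spatial correlation. Includes a synthetic random-foraging trajectory
    generator, hysteresis/learning-rate protocols, grid-cell realignment, and
    parametric search over the network's mixing and recall parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
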