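Package: clawpore
Title: Claudin Cis/Trans Assembly Landscapes, Paracellular Pore Profiling and
    Barrier Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for tight-junction claudin complexes. Reduces
    PDB structures to one-bead-per-residue rigid models with residue charges,
    computes rotational cis-interaction energy landscapes (Lennard-Jones +
    Coulomb) with stable-state and pore-forming-window statistics, assembles
    symmetric trans tetramers with interface-energy decomposition, profiles
    the paracellular pore (maximal inscribed probe radius along the channel
    axis), classifies pore-lining residues by charge, and implements
    barrier-function arithmetic: TEER correction, Goldman-Hodgkin-Katz
    dilution and bi-ionic potential inversion, absolute permeabilities from
    conductance, and apparent permeability from tracer flux. Includes
    synthetic generators (claudin-like toy monomers, ring stacks with
    analytic pore radii, forward-simulated electrophysiology and flux
    records) so every stage is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
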