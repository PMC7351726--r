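Package: dockpull
Title: Post-Docking Thermodynamics, Interaction Fingerprints and
    Coarse-Grained Ligand Pulling for a GSK-3beta Inhibitor Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-docking computational analysis of an indirubin-3'-oxime
    inhibitor series against glycogen synthase kinase-3 beta (GSK-3beta):
    thermodynamic conversion between docking scores, inhibition constants
    and IC50-derived experimental binding free energies with correlation
    and regression summaries; Ertl fragment-based topological polar
    surface area and molar mass from atom-typed molecular graphs;
    geometric hydrogen-bond and 5 Angstrom contact fingerprints of
    protein-ligand complexes; and a coarse-grained fast-pulling-of-ligand
    (FPL) engine using Langevin dynamics in a Lennard-Jones plus Coulomb
    pocket, with the replica-averaged interaction-energy-difference
    estimator of binding. Ships the study's published tables as plain-text
    fixtures and synthetic generators with known ground truth for every
    downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
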