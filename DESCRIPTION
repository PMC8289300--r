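Package: cdslab
Title: Cyclodextrin-Protein Trajectory Analysis at Air-Water and Ice-Water Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse molecular-dynamics trajectories of proteins
    formulated with cyclodextrin excipients in slab geometries. Computes
    normalized interfacial density profiles, cyclodextrin rim-orientation
    profiles and proximity-count convergence series; detects inclusion of
    protein residues in cyclodextrin cavities and cyclodextrin
    self-aggregation; evaluates the collective variables used in
    parallel-bias metadynamics (radius of gyration, alpha-helix content,
    protein-interface distance, distance-RMSD); reweights biased
    trajectories with the Tiwary-Parrinello estimator; and maps
    conformationally unstable patches via GROMOS (Daura) clustering,
    Kabsch superposition and per-residue Q scores. A synthetic-data module
    generates slab trajectories with planted statistical structure,
    RMSD-controlled conformational ensembles and a one-dimensional
    well-tempered metadynamics toy sampler, so the whole pipeline is
    testable without running a molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    bio3d,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
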