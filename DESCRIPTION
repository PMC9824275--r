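Package: npfibril
Title: Coarse-Grained Nanoplastic-Amyloid Fibril Interaction Modelling and Contact Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builders for coarse-grained polystyrene, polyethylene and
    polypropylene nanoparticle models (neutral and surface-charged), a
    coarse-grained beta-amyloid (Abeta42) cross-beta fibril model with
    residue-class and charge annotation, a rigid-body overdamped Langevin
    simulator of nanoparticle-fibril encounters in a periodic box, and the
    analysis operators used to characterise such encounters: cutoff contact
    counting (0.8 nm), residue-class breakdowns, per-residue contact
    frequency profiles, side versus frontal contact classification, and a
    moment-of-inertia shape factor. Structures are read and written as GRO,
    PDB (including multi-model trajectories) and XYZ; reports as CSV/JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    bio3d,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
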