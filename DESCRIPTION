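Package: cglipidsite
Title: Lipid Binding-Site Mapping on Membrane Proteins from Coarse-Grain Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for coarse-grain molecular dynamics
    trajectories of membrane proteins in lipid bilayers, built around the
    analyses used to locate and quantify a sphingolipid binding site on a
    beta-barrel channel: residue-resolved head-group contact occupancy under
    periodic boundaries, per-ligand binding-event detection with majority-vote
    smoothing and end-censoring, time-weighted residence-time distributions
    with bootstrap confidence intervals and rank-based comparisons, in-plane
    protein alignment with three-dimensional occupancy-volume gridding and
    OpenDX export, and a telegraph-process trajectory generator with exact
    ground-truth kinetics for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
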