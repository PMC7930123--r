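Package: lipocontact
Title: Lipid-Channel Contact Mapping, Membrane Biophysics, and
    Electrophysiology Curve Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-simulation analysis of lipid modulation of ion channels.
    Computes per-residue lipid contact metrics (contact-duration and
    maximum-occupancy) from coarse-grained or atomistic trajectories,
    selects interaction hot spots with boxplot statistics (upper quartile
    and Q3 + 1.5*IQR outliers) aggregated over tetramer subunits and
    replicas, and provides a bilayer property suite: density profiles,
    thickness, grid-tessellation areas per lipid, lateral diffusion from
    mean-square displacement, headgroup clustering, flip-flop detection,
    and geometric hydrogen bonds. A companion electrophysiology layer fits
    Boltzmann activation curves, exponential deactivation kinetics, and
    plateau-anchored Hill dose-response curves. Synthetic trajectory and
    recording generators with exact ground truth make every stage testable
    without molecular dynamics runs or patch-clamp data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
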