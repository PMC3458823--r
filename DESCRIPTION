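Package: fibmap
Title: Panoramic Phase Mapping of Atrial Fibrillation Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational mapping of atrial fibrillation from panoramic
    multielectrode (basket-catheter) recordings: activation-time detection with
    restitution-based interval filtering, per-cycle isochronal maps and
    conduction-velocity estimation, Hilbert-transform phase maps,
    topological-charge phase-singularity detection and tracking, and
    rotor/focal-source characterization (migration loci, areas, temporal
    conservation). Includes a two-variable excitable-medium simulator that
    generates spiral-wave, focal and plane-wave episodes with ground truth,
    sampled as pseudo-unipolar electrograms on basket-like electrode grids, so
    the whole mapping chain can be validated against known source locations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    interp,
    jsonlite,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
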