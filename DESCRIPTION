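Package: spinedyn
Title: Longitudinal Dendritic Spine Dynamics from Two-Photon Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of longitudinal in-vivo two-photon imaging
    of dendritic spines. Generates ground-truthed synthetic fluorescence z-stacks
    of dsRed-labeled apical dendrites, traces the dendritic backbone with local
    radius, attaches spine endpoints to the backbone along the brightest linear
    path, applies protrusion-length and orientation inclusion filters, matches
    spines across imaging sessions by arc-length position, and computes spine
    density, addition, elimination and turnover ratios together with normalized
    spine-intensity statistics. Also provides Sholl profiles and reconstruction
    summaries for SWC morphologies, novel-object-recognition preference index,
    Y-maze spontaneous alternation, and 2^-ddCt qPCR fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
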