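Package: corelandscape
Title: Conformational Landscapes, Rigid-Body Modes and Pore Geometry of
    Barrel-Shaped Protein Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the conformational variability of large
    barrel-shaped protein assemblies such as the 26S proteasome from
    coarse-grained particle ensembles. Builds synthetic bead-model
    ensembles with configurable rigid-body modes (lid rotation and tilt,
    core compression, subunit swings), converts particle populations over
    mode coordinates into Boltzmann-inverted free-energy landscapes with
    watershed basin detection and minimax barrier analysis, recovers
    rigid-body motion descriptors (rotation angle, screw axis, pivot,
    amplitude) by least-squares superposition, detects and measures wall
    pores and the axial gate of a closed barrel on an occupancy grid, and
    evaluates a hindered-diffusion model of peptide release through
    narrow pores. All user-facing functions take and return tidy data
    frames.
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
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
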