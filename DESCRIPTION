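Package: pvsmap
Title: Perivascular Space Mapping and Cognitive-Network Burden Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments enlarged perivascular spaces (PVS) from co-registered
    T2-weighted brain MRI by local intensity contrast, clusters supra-threshold
    voxels under 26-connectivity, and quantifies PVS count, volume (in voxels)
    and diameter per parcellation region and per cognitive network (default
    mode, central executive/frontoparietal, salience). Includes a phantom MRI
    generator with ground-truth tubular PVS structures, a synthetic cohort
    generator with configurable network-specific burden effects, and an
    extreme-of-outcome Mann-Whitney group analysis rendered as a
    yellow/orange/red severity map.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
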