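Package: fcnm
Title: Functional Connectivity Network Mapping from Activation Coordinates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps literature-reported brain activation coordinates to consensus
    resting-state networks using a normative functional connectome. Spherical
    seeds built around reported foci are correlated with every brain voxel in
    each subject of the connectome, Fisher z-transformed, tested with a
    voxel-wise one-sample t-test under Benjamini-Hochberg false discovery rate
    control, binarized, and overlaid across studies into probability maps that
    are thresholded to define the consensus network. Downstream tools decompose
    networks into canonical cortical systems, correlate them with
    neurotransmitter receptor and transporter density maps via rank-based
    partial correlation with permutation p-values, and validate robustness with
    Dice overlap across seed radii and datasets. A synthetic-data module
    generates connectomes, foci tables, atlases, parcellations, and receptor
    catalogues with known ground truth so the whole pipeline is testable
    without any neuroimaging downloads.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
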