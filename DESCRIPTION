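Package: coaltnet
Title: Morphometric Co-Alteration Networks and Connectivity-Profile
    Parcellation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds morphometric co-alteration networks from
    coordinate-based voxel-based-morphometry experiments: modeled-alteration
    maps and their anatomical-likelihood-estimation (ALE) union, 3D peak
    detection, Patel's kappa co-alteration edges, root-node identification
    inside a region-of-interest mask, hierarchical (WPGMA) clustering of
    root-node co-alteration profiles, voxel-wise nearest-root parcellation,
    classical multidimensional scaling, and functional-network
    decomposition. Includes a synthetic-data generator with planted
    co-alteration structure so the whole pipeline is testable without
    proprietary coordinate databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
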