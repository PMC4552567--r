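Package: angioscale
Title: Vessel Network Extraction and Vascular Scaling Exponents from 3D Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Extracts blood-vessel networks from 3D tomographic angiography
    volumes (NIfTI, NRRD, TIFF stacks) by intensity thresholding,
    connectivity-preserving erosion skeletonization, and centerline-based
    segment decomposition, yielding per-segment radius, length, volume and
    topology. Estimates vascular scaling exponents for radius and length by
    four methods: per-junction conservation-law solutions of the generalized
    Murray's law, child/parent scale-factor ratios, power-law fits to the
    size distribution, and standard major axis regression against the number
    of downstream tips. Includes synthetic self-similar tree tables and
    voxelized tube-tree phantoms with ground truth, plus threshold and noise
    sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    tiff,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
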