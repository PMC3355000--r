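Package: nirsmc
Title: Voxelized Time-Resolved Monte Carlo Simulation of Near-Infrared
    Light Transport in Five-Layer Head Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for patient-oriented near-infrared spectroscopy (NIRS)
    probe design. Builds five-layer voxel head models (scalp, skull,
    cerebrospinal fluid, gray matter, white matter) either from synthetic
    phantoms or by segmenting a T1-like intensity volume with a variational
    level-set contour, region growing and mixture-of-Gaussians maximum
    probability classification. Runs a three-dimensional time-resolved
    Monte Carlo photon-packet simulation with Henyey-Greenstein scattering,
    Fresnel/Snell boundary handling and full per-layer path bookkeeping,
    and derives NIRS design outputs: spatial sensitivity profiles, detected
    intensity versus source-detector separation, layer-ratio curves and the
    surface/cortex cross-point separation, at multiple wavelengths.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    EBImage,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'volumes.R'
    'probe_layout.R'
    'tissue_table.R'
    'mc_ops.R'
    'simulate.R'
    'analysis.R'
    'region_grow.R'
    'mixture.R'
    'level_set.R'
    'segment.R'
    'phantoms.R'
    'config.R'
    'nirsmc-package.R'
    'volume_io.R'
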