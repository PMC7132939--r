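Package: mvbquant
Title: Morphometry, Stereology and 3D Spatial Statistics for Organelles
    in Volume Electron Microscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of membrane-bound organelles (such as
    multivesicular bodies) segmented from FIB-SEM image stacks of neural
    tissue. Provides object morphometry from labeled voxel volumes with
    anisotropic voxel geometry and tissue-shrinkage correction, unbiased
    density estimation with a three-dimensional counting frame, Cavalieri
    point-grid volume-fraction estimation, log-normal size-distribution
    fitting, compartment concentration analysis with the accompanying
    hypothesis tests, and 3D spatial point-pattern statistics (G, F and K
    functions) with Monte-Carlo envelopes against complete spatial
    randomness. A synthetic-data module generates ground-truth catalogs,
    point patterns and voxel phantoms so every estimator can be validated
    by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
biocViews: Software, CellBiology, Spatial, Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'generate-catalog.R'
    'generate-points.R'
    'io.R'
    'methods-accessors.R'
    'morphometry.R'
    'mvbquant-package.R'
    'pipeline.R'
    'render-stack.R'
    'spatial.R'
    'stats.R'
    'stereology.R'
    'utils-geometry.R'
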