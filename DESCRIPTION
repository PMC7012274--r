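Package: hant
Title: Hierarchical Ant Colony Clustering for fMRI Region-of-Interest
    Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies regions of interest (ROIs) in functional MRI by
    hierarchical ant colony clustering. BOLD voxel time series are
    detrended, deconvolved against the canonical Glover haemodynamic
    response function to recover latent neural events, grouped by
    anatomical atlas label, embedded in two dimensions (UMAP or PCA),
    and clustered within each label by simulated ants whose pick-up and
    drop probabilities follow local-similarity rules on a toroidal grid.
    The number of ROIs per label is fixed automatically by a
    density-based criterion on a k-nearest-neighbour graph. Includes a
    dynamic-causal-model (DCM) BOLD simulator with controlled
    signal-to-noise ratio for validation, cluster-validity metrics
    (silhouette, Davies-Bouldin), a parameter grid search, and NIfTI
    import/export of volumes and parcellations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    uwot,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr,
    Matrix
Config/testthat/edition: 3
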