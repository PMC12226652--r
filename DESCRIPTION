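Package: PCDRadiomics
Title: Robustness of Radiomics Texture Features on Simulated Photon-Counting CT Phantom Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a 28-material texture phantom imaged under a 13-protocol
    photon-counting CT acquisition/reconstruction matrix (repositioning,
    high-pitch scanning, tube voltage, slice thickness, dose level, iterative
    reconstruction strength and kernel, modelled as image-domain perturbations),
    extracts the 93-feature radiomics set (18 first-order plus GLCM, GLRLM,
    GLSZM, GLDM and NGTDM texture families) with fixed-bin-width gray-level
    discretization, and quantifies per-feature robustness with the two-way
    absolute-agreement intraclass correlation coefficient, Lin's concordance
    correlation coefficient, the coefficient of variation and the quartile
    coefficient of dispersion, including interpretation bins and study-level
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'PCDRadiomics-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'protocols.R'
    'acquisition.R'
    'discretize.R'
    'texturefeatures.R'
    'firstorder.R'
    'extract.R'
    'texture.R'
    'groundtruth.R'
    'stats.R'
    'roi.R'
    'pipeline.R'
    'io.R'
    'materials.R'
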