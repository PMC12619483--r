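Package: qctemph
Title: Quantitative CT Emphysema Metrics and Lobar Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative computed tomography (QCT) analysis of pulmonary
    emphysema on lobe-labelled chest CT volumes, aimed at phenotyping in
    alpha-1-antitrypsin deficiency (AATD). Computes voxel-level density
    metrics (mean lung density, emphysema index at a -950 HU threshold,
    15th-percentile density, lung volume) and cluster-morphology indices
    (ET1 bulk, ET2 subpleural fraction, ET3 panlobular fraction) for the
    whole lung, each lung and each of six lobes; aggregates lobar emphysema
    indices into three zones and classifies the distribution as homogeneous
    or heterogeneous with an upper, middle-lobe/lingula or lower-lobe
    predominance; and provides the cohort statistics layer (serum-level
    grouping, descriptive group comparisons, stepwise binary logistic
    regression for middle-lobe/lingula-predominant emphysema). Includes
    seeded generators for CT-like lung phantoms with known emphysema ground
    truth and for synthetic AATD cohorts with planted covariate effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
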