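Package: immunotopo
Title: Spatial Immune Topography of Solid Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial organization of tumor-infiltrating immune
    cells from annotated tumor boundaries and cell centroids. Builds the three
    canonical compartments (tumor core, inner and outer 500 micrometre invasive
    margins) by polygon erosion and dilation, computes per-compartment cell
    densities in cells per square millimetre, classifies slides into cold,
    immune-excluded and hot topographies against pooled median cutoffs,
    forms bivariate lymphoid-myeloid phenotype grids, runs an optimal
    cluster-number protocol (Gaussian mixture, k-means and hierarchical
    clustering scored by Davies-Bouldin, Calinski-Harabasz and silhouette
    criteria), and stratifies survival by bivariate phenotype with
    multivariable Cox models, Kaplan-Meier curves and log-rank tests. A
    synthetic-cohort generator produces tumor geometries, inhomogeneous
    Poisson cell patterns with known topography archetypes, and survival
    outcomes with known hazard ratios, so the full pipeline is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    spatstat.geom,
    jsonlite,
    yaml,
    survival,
    cluster,
    mclust,
    ape,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
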