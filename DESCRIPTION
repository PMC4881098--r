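Package: topomort
Title: Village-Scale Spatial Analysis of Disease Mortality and Topography
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for small-area disease-mapping studies that relate
    village-level mortality to terrain. Computes DEM-derived topographic
    indices (relief degree of land surface, RDLS; village dwelling
    condition, VDC) from focal and zonal raster statistics, smooths crude
    mortality rates with the spatial (locally varying reference mean)
    empirical Bayes estimator, quantifies spatial structure with global
    Moran's I (permutation and analytic inference) and local Getis-Ord
    Gi* hotspot classification, and links mortality to terrain through
    Pearson correlation and geographically weighted regression with AICc
    bandwidth selection and model comparison. Includes a synthetic-study
    generator (basin-shaped DEM, Voronoi village tessellation,
    flatness-biased residential placement, Poisson mortality with a
    terrain-driven log-risk surface) so the full pipeline is testable
    without survey data, plus readers and writers for ESRI ASCII grids,
    GeoJSON village polygons and mortality CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'correlation.R'
    'geometry.R'
    'gistar.R'
    'grid-io.R'
    'gwr.R'
    'moran.R'
    'pipeline.R'
    'rates.R'
    'synthetic.R'
    'terrain.R'
    'topomort-package.R'
    'vector-io.R'
    'weights.R'
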