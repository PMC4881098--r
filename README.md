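# topomort

Village-scale spatial analysis of disease mortality and topography.

Small-area studies of environmentally driven disease — the motivating case
is lung-cancer mortality in a mountainous coal-burning region — ask whether
death rates are structured by terrain: valley "pockets" trap combustion
aerosols, people settle the scarce flat ground, and both concentrate
exposure. `topomort` implements the complete analytical chain for such a
study at the administrative-village scale, for epidemiologists and health
geographers working with a DEM, village polygons, a residential layer and
per-village death counts.

## What it computes

**Terrain indices.** Relatively flat areas (RFA) are cells whose 3×3
focal elevation range is ≤ 30 m. Per village, the dwelling condition

    VDC = VRA_f / VRA            (flat residential area / residential area)

and the relief degree of land surface

    RDLS = ALT/1000 + Range(H) · [1 − P(A)/A] / BM,      BM = 500 m

from zonal statistics over the DEM (`focalRange`, `extractRFA`,
`zonalTopography`, `computeVDC`, `computeRDLS`).

**Rate smoothing.** Crude rates per 10⁵ are shrunk toward a locally varying
reference mean (spatial empirical Bayes): local mean m_i and prior variance
s_i² over each village's contiguity neighborhood (self included), weight
w_i = s_i²/(s_i² + m_i/p_i), estimate w_i·r_i + (1−w_i)·m_i; then five-fold
categorization against a reference rate R0 (`spatialEBSmooth`,
`categorizeRates`, `adjustUnderreporting`).

**Spatial clustering.** Binary queen/rook contiguity weights built from the
polygons (`buildContiguityWeights`); global Moran's I with permutation or
analytic inference (`moransITest`); local Getis–Ord Gi* z-scores with
95%/99% hot/cold classification and persistent (every-period) hotspots
(`giStar`, `classifyHotspots`, `persistentHotspots`).

**Association.** Pearson correlations of smoothed rates with RDLS/VDC, and
geographically weighted regression with adaptive-bisquare or fixed-Gaussian
kernels, AICc golden-section bandwidth selection, hat-matrix diagnostics,
standardized residuals and AICc model comparison across covariate subsets
(`fitGWR`, `selectBandwidth`, `compareGWRModels`, `stdresidCoverage`).

**Synthetic studies.** `simulateStudy()` generates a full study with known
truth — a plateau holding one pocket-like basin (smooth floor, rough
massif), Voronoi villages, flatness-biased residences, and Poisson deaths
whose log-risk rises with VDC and falls with RDLS — so the pipeline is
testable without survey data and parameter recovery is demonstrated, not
assumed.

Inputs are plain formats: ESRI ASCII grids, GeoJSON polygons
(`village_id` property), long-format mortality CSV, YAML configs. A thin
CLI lives at `inst/scripts/topomort`
(`simulate | terrain | rates | cluster | gwr | run-all`).

## Worked example

```r
library(topomort)

study <- simulateStudy(syntheticConfig(seed = 1))   # 300 villages, 3 periods
dir <- tempfile(); writeStudy(study, dir)

cfg <- analysisConfig(dem         = file.path(dir, "dem.asc"),
                      villages    = file.path(dir, "villages.geojson"),
                      residential = file.path(dir, "residential.asc"),
                      mortality   = file.path(dir, "mortality.csv"),
                      R0 = 25, seed = 1, outdir = file.path(dir, "out"))
res <- runPipeline(cfg)

res$moran
#>          attribute     I z_perm p_perm z_analytic p_analytic   n
#> 1 smoothed_rate_P1 0.511   15.0  0.002      15.05   3.47e-51 300
#> 2 smoothed_rate_P2 0.469   13.8  0.002      13.87   1.02e-43 300
#> 3 smoothed_rate_P3 0.630   18.1  0.002      18.50   2.21e-76 300
#> 4             RDLS 0.703   20.1  0.002      20.63   1.35e-94 300
#> 5              VDC 0.148    4.5  0.002       4.42   9.91e-06 300

res$correlations
#>   period      pair      r  p_value   n
#> 1     P1 rate~RDLS -0.583 9.37e-29 300
#> 2     P1  rate~VDC  0.641 4.38e-36 300
#> ...
#> 7    all  RDLS~VDC -0.510 3.12e-21 300

subset(res$gwr, period == "P3")
#>  period variant covariates bandwidth AICc    R2  adjR2 stdres_cover
#>      P3     VDC        VDC        22 3059 0.820 0.7409       0.9633
#>      P3    both   RDLS+VDC        32 3100 0.785 0.6983       0.9667
#>      P3    RDLS       RDLS        22 3179 0.715 0.6024       0.9467
```

Reading the output: mortality, RDLS and VDC are all spatially clustered
(positive Moran's I, permutation p = 0.002 at 999 draws); the smoothed rate
rises with dwelling condition (r ≈ +0.6) and falls with relief (r ≈ −0.6),
and the two terrain indices oppose each other (r ≈ −0.5) — the designed
risk structure, recovered end to end. The VDC-only GWR variant carries the
lowest AICc, with ~96% of standardized residuals inside [−2, 2]; the
basin's persistent hotspot core (38 villages here) is listed in
`res$persistent_hotspots`. All tables are also written as CSV/GeoJSON under
`outdir`, with the run log recording the config hash and seed.

See `vignettes/topomort-methods.Rmd` for the full model description,
parameter meanings and design decisions.

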