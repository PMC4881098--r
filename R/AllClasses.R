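#' @import methods
NULL

#' DEMGrid: a projected elevation raster
#'
#' Minimal raster container for a digital elevation model on a regular,
#' projected grid (cells in meters). Values are stored as a numeric matrix in
#' row-major map order: row 1 is the northernmost row, column 1 the
#' westernmost column. Cell centers are at
#' \code{x = xmin + (col - 0.5) * cellSize} and
#' \code{y = ymax - (row - 0.5) * cellSize}, where \code{origin = c(xmin, ymax)}
#' is the top-left corner of the grid.
#'
#' @slot values numeric matrix of elevations (m); \code{NA} marks nodata.
#' @slot cellSize positive cell edge length in meters.
#' @slot origin numeric(2), map coordinates of the top-left grid corner.
#' @slot nodata numeric sentinel used on disk (in memory nodata is \code{NA}).
#' @slot crs free-text note identifying the projected CRS.
#'
#' @seealso [DEMGrid()], [readAsciiGrid()], [focalRange()]
#' @exportClass DEMGrid
setClass("DEMGrid",
  representation(
    values = "matrix",
    cellSize = "numeric",
    origin = "numeric",
    nodata = "numeric",
    crs = "character"
  ),
  prototype(
    values = matrix(numeric(0), 0, 0),
    cellSize = 100,
    origin = c(0, 0),
    nodata = -9999,
    crs = "local projected CRS (meters)"
  )
)

setValidity("DEMGrid", function(object) {
  msg <- character(0)
  if (!is.numeric(object@values))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "'cellSize' must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be two finite coordinates (xmin, ymax)")
  if (any(is.infinite(object@values)))
    msg <- c(msg, "elevations must be finite where not nodata (NA)")
  if (length(msg)) msg else TRUE
})

#' ResidentialMask: binary raster of residential cells
#'
#' A [DEMGrid-class] whose values are 0/1 (1 = residential), aligned cell-for-
#' cell with the DEM it annotates.
#'
#' @exportClass ResidentialMask
setClass("ResidentialMask", contains = "DEMGrid")

setValidity("ResidentialMask", function(object) {
  v <- object@values
  bad <- !is.na(v) & !(v %in% c(0, 1))
  if (any(bad)) "mask values must be 0, 1 or NA" else TRUE
})

#' VillageSet: village polygons with stable identifiers
#'
#' Polygons are simple rings stored as two-column (x, y) coordinate matrices
#' in projected meters; the ring need not repeat its first vertex. Areas are
#' kept in km2 as used throughout the terrain indices.
#'
#' @slot ids character vector of unique village identifiers.
#' @slot polygons list of numeric matrices (one ring per village).
#' @slot areas numeric vector of polygon areas in km2.
#'
#' @seealso [villageSet()], [generateVillages()], [buildContiguityWeights()]
#' @exportClass VillageSet
setClass("VillageSet",
  representation(ids = "character", polygons = "list", areas = "numeric")
)

setValidity("VillageSet", function(object) {
  msg <- character(0)
  n <- length(object@ids)
  if (anyDuplicated(object@ids))
    msg <- c(msg, "village ids must be unique")
  if (length(object@polygons) != n || length(object@areas) != n)
    msg <- c(msg, "ids, polygons and areas must have equal length")
  ok <- vapply(object@polygons, function(p)
    is.matrix(p) && ncol(p) == 2L && nrow(p) >= 3L && all(is.finite(p)),
    logical(1))
  if (!all(ok))
    msg <- c(msg, "each polygon must be a finite 2-column matrix with >= 3 vertices")
  if (any(!is.finite(object@areas) | object@areas <= 0))
    msg <- c(msg, "areas must be positive")
  if (length(msg)) msg else TRUE
})

#' SpatialWeights: binary contiguity matrix over villages
#'
#' Square 0/1 matrix ordered like \code{ids}. Symmetric; the diagonal is zero
#' unless \code{includeSelf} (the Gi* convention).
#'
#' @slot ids ordered village ids.
#' @slot w binary numeric matrix.
#' @slot rule "queen" or "rook".
#' @slot includeSelf logical flag.
#' @exportClass SpatialWeights
setClass("SpatialWeights",
  representation(ids = "character", w = "matrix", rule = "character",
                 includeSelf = "logical")
)

setValidity("SpatialWeights", function(object) {
  msg <- character(0)
  n <- length(object@ids)
  w <- object@w
  if (!all(dim(w) == c(n, n)))
    msg <- c(msg, "weight matrix dimensions must match ids")
  if (anyDuplicated(object@ids))
    msg <- c(msg, "village ids must be unique")
  if (n > 0) {
    if (!all(w %in% c(0, 1)))
      msg <- c(msg, "weights must be binary 0/1")
    else {
      if (!isTRUE(all.equal(w, t(w))))
        msg <- c(msg, "weight matrix must be symmetric")
      d <- diag(w)
      if (!object@includeSelf && any(d != 0))
        msg <- c(msg, "diagonal must be zero when includeSelf is FALSE")
      if (object@includeSelf && any(d != 1))
        msg <- c(msg, "diagonal must be one when includeSelf is TRUE")
    }
  }
  if (!object@rule %in% c("queen", "rook"))
    msg <- c(msg, "rule must be 'queen' or 'rook'")
  if (length(msg)) msg else TRUE
})

#' MoranResult: global Moran's I with inference
#'
#' @slot I observed Moran's I statistic.
#' @slot expectation expected value under the null, -1/(n-1).
#' @slot zScore standardized deviate (permutation or analytic).
#' @slot pValue two-sided p-value.
#' @slot method "permutation" or "analytic".
#' @slot nPerm number of permutations (0 for analytic).
#' @slot seed RNG seed used for permutation (NA for analytic).
#' @slot n number of spatial units.
#' @exportClass MoranResult
setClass("MoranResult",
  representation(I = "numeric", expectation = "numeric", zScore = "numeric",
                 pValue = "numeric", method = "character", nPerm = "integer",
                 seed = "integer", n = "integer")
)

setValidity("MoranResult", function(object) {
  msg <- character(0)
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (!object@method %in% c("permutation", "analytic"))
    msg <- c(msg, "method must be 'permutation' or 'analytic'")
  if (length(msg)) msg else TRUE
})

#' GWRResult: a fitted geographically weighted regression
#'
#' Local coefficients are reported on the raw covariate scale; when the fit
#' standardized covariates internally, the standardized-scale coefficients are
#' kept alongside. Global diagnostics follow the usual hat-matrix quantities:
#' effective parameters \code{v1 = tr(S)}, \code{v2 = tr(S'S)}, corrected
#' Akaike score AICc, and standardized residuals
#' \code{e_i / (sigma * sqrt(1 - s_ii))}.
#'
#' @slot localCoef n x p matrix of raw-scale local coefficients.
#' @slot localCoefStd local coefficients on the standardized scale.
#' @slot fitted,residuals,stdResiduals,localR2,hatDiag per-location vectors.
#' @slot coords n x 2 matrix of observation coordinates.
#' @slot kernel kernel name; @slot adaptive logical; @slot bandwidth numeric.
#' @slot v1,v2 effective-parameter traces; @slot RSS residual sum of squares.
#' @slot R2,adjR2,AICc global fit summaries.
#' @slot xNames covariate names (including "(Intercept)").
#' @exportClass GWRResult
setClass("GWRResult",
  representation(
    localCoef = "matrix", localCoefStd = "matrix", fitted = "numeric",
    residuals = "numeric", stdResiduals = "numeric", localR2 = "numeric",
    hatDiag = "numeric", coords = "matrix", kernel = "character",
    adaptive = "logical", bandwidth = "numeric", v1 = "numeric",
    v2 = "numeric", RSS = "numeric", R2 = "numeric", adjR2 = "numeric",
    AICc = "numeric", xNames = "character"
  )
)

setValidity("GWRResult", function(object) {
  msg <- character(0)
  if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
    msg <- c(msg, "bandwidth must be a single positive value (Inf allowed)")
  if (is.finite(object@adjR2) && is.finite(object@R2) &&
      object@adjR2 > object@R2 + 1e-10)
    msg <- c(msg, "adjusted R2 cannot exceed R2")
  if (length(msg)) msg else TRUE
})

#' SyntheticConfig: parameters of the synthetic-study generator
#'
#' Defaults emulate the study conditions the pipeline is designed for: a
#' mountainous plateau (~2192 m) holding one pocket-like basin (~170 m deep,
#' radius 30 cells) on a 120 x 120 grid of 100 m cells; 300 Voronoi villages
#' with populations between 500 and 5000 (well below the 30,000 bound that
#' motivates rate smoothing); residential cells biased 4-fold toward
#' relatively flat terrain; and Poisson deaths whose log-risk rises with VDC
#' and falls with RDLS around a baseline of 88 per 100,000 per period.
#'
#' @slot gridRows,gridCols grid dimensions (cells).
#' @slot cellSize cell edge (m).
#' @slot basinCenter row/col of the basin center (cells).
#' @slot basinRadius basin radius (cells).
#' @slot basinDepth basin depth (m).
#' @slot plateau plateau elevation (m).
#' @slot trendRange total elevation drop of the regional trend across the
#'   grid (m).
#' @slot roughnessSd standard deviation of the correlated terrain noise (m).
#' @slot roughnessKernel Gaussian smoothing radius of the noise, in cells.
#' @slot nVillages number of villages.
#' @slot popRange min/max village population (persons).
#' @slot resFraction fraction of a village's cells that are residential.
#' @slot flatBias sampling-odds multiplier for flat cells in residential
#'   placement.
#' @slot baselineRate typical-village death rate per 1e5 person-periods.
#' @slot betaVdc log-risk slope per unit VDC (> 0 in the study design).
#' @slot betaRdls log-risk slope per unit RDLS (< 0 in the study design).
#' @slot noiseSd standard deviation of the spatially correlated log-risk
#'   noise.
#' @slot noiseRange Gaussian range (m) of the log-risk noise field.
#' @slot nPeriods number of observation periods.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    gridRows = "integer", gridCols = "integer", cellSize = "numeric",
    basinCenter = "numeric", basinRadius = "numeric", basinDepth = "numeric",
    plateau = "numeric", trendRange = "numeric", roughnessSd = "numeric",
    roughnessKernel = "numeric", nVillages = "integer", popRange = "numeric",
    resFraction = "numeric", flatBias = "numeric", baselineRate = "numeric",
    betaVdc = "numeric", betaRdls = "numeric", noiseSd = "numeric",
    noiseRange = "numeric", nPeriods = "integer", seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character(0)
  if (object@gridRows < 1L || object@gridCols < 1L)
    msg <- c(msg, "grid dimensions must be positive")
  if (object@cellSize <= 0)
    msg <- c(msg, "cellSize must be positive")
  if (max(object@popRange) >= 30000)
    msg <- c(msg, "village populations must stay below 30,000")
  if (min(object@popRange) < 0 || object@popRange[1] > object@popRange[2])
    msg <- c(msg, "popRange must be 0 <= min <= max")
  ext <- min(object@gridRows, object@gridCols)
  if (object@basinRadius * 2 >= ext)
    msg <- c(msg, "basin diameter must be smaller than the grid extent")
  if (object@nVillages < 1L)
    msg <- c(msg, "nVillages must be positive")
  if (object@nPeriods < 1L)
    msg <- c(msg, "nPeriods must be positive")
  if (object@baselineRate <= 0)
    msg <- c(msg, "baselineRate must be positive")
  if (object@flatBias <= 0)
    msg <- c(msg, "flatBias must be positive")
  if (object@resFraction <= 0 || object@resFraction > 1)
    msg <- c(msg, "resFraction must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticStudy: a complete simulated study
#'
#' @slot dem [DEMGrid-class] terrain.
#' @slot villages [VillageSet-class] tessellation.
#' @slot residential [ResidentialMask-class] residential cells.
#' @slot topography per-village terrain table (as from [zonalTopography()]).
#' @slot mortality long-format data.frame: village_id, period, deaths,
#'   population.
#' @slot truth list holding the generating risk surface (expected rates,
#'   slopes, noise field) for parameter-recovery checks.
#' @slot config the [SyntheticConfig-class] used.
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
  representation(
    dem = "DEMGrid", villages = "VillageSet", residential = "ResidentialMask",
    topography = "data.frame", mortality = "data.frame", truth = "list",
    config = "SyntheticConfig"
  )
)

setValidity("SyntheticStudy", function(object) {
  msg <- character(0)
  m <- object@mortality
  need <- c("village_id", "period", "deaths", "population")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("mortality must have columns:",
                        paste(need, collapse = ", ")))
  else if (any(m$deaths > m$population))
    msg <- c(msg, "deaths cannot exceed population")
  if (length(msg)) msg else TRUE
})
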