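#' Configure the synthetic-study generator
#'
#' Builds a [SyntheticConfig-class] with defaults emulating the study design
#' the pipeline targets: a high plateau holding one pocket-like basin ringed
#' by higher terrain, ~300 villages with small populations, residential
#' placement biased toward flat cells, and Poisson mortality whose log-risk
#' increases with VDC and decreases with RDLS.
#'
#' @param gridRows,gridCols grid size in cells (default 120 x 120).
#' @param cellSize cell edge in meters (default 100).
#' @param basinCenter c(row, col) of the basin center (default grid center).
#' @param basinRadius basin radius in cells (default 30).
#' @param basinDepth basin depth in meters (default 200, putting the basin
#'   floor mean about 170 m below the surrounding ring).
#' @param plateau plateau elevation in meters (default 2192).
#' @param trendRange total west-east drop of the regional trend (m).
#' @param roughnessSd sd of the correlated terrain noise (m).
#' @param roughnessKernel Gaussian smoothing radius of that noise (cells).
#' @param nVillages number of villages (default 300).
#' @param popRange min/max village population (default 500-5000, below the
#'   30,000 bound that motivates rate smoothing).
#' @param resFraction fraction of each village's cells made residential.
#' @param flatBias sampling-odds multiplier for flat cells (default 4).
#' @param baselineRate typical-village rate per 1e5 person-periods.
#' @param betaVdc,betaRdls log-risk slopes (positive / negative by design).
#' @param noiseSd sd of the spatially correlated log-risk noise.
#' @param noiseRange Gaussian range of that noise in meters.
#' @param nPeriods number of periods (default 3).
#' @param seed integer seed; all generator stages derive their streams from
#'   it (stage offsets: DEM +1, villages +2, residences +3, mortality +4).
#' @return a validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(gridRows = 120L, gridCols = 120L, cellSize = 100,
                            basinCenter = NULL, basinRadius = 30,
                            basinDepth = 200, plateau = 2192,
                            trendRange = 30, roughnessSd = 55,
                            roughnessKernel = 2, nVillages = 300L,
                            popRange = c(500, 5000), resFraction = 0.04,
                            flatBias = 4, baselineRate = 88,
                            betaVdc = 1.5, betaRdls = -0.6, noiseSd = 0.15,
                            noiseRange = 1500, nPeriods = 3L, seed = 1L) {
  if (is.null(basinCenter)) basinCenter <- c(gridRows, gridCols) / 2
  new("SyntheticConfig",
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      cellSize = cellSize, basinCenter = as.numeric(basinCenter),
      basinRadius = basinRadius, basinDepth = basinDepth, plateau = plateau,
      trendRange = trendRange, roughnessSd = roughnessSd,
      roughnessKernel = roughnessKernel, nVillages = as.integer(nVillages),
      popRange = as.numeric(popRange), resFraction = resFraction,
      flatBias = flatBias, baselineRate = baselineRate, betaVdc = betaVdc,
      betaRdls = betaRdls, noiseSd = noiseSd, noiseRange = noiseRange,
      nPeriods = as.integer(nPeriods), seed = as.integer(seed))
}

# run expr under a given seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# row/column Gaussian smoothing matrix with edge renormalization
.smoothMatrix <- function(n, radius) {
  if (radius <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * radius))
  K <- outer(seq_len(n), seq_len(n), function(i, j) {
    d <- abs(i - j)
    ifelse(d <= half, exp(-0.5 * (d / radius)^2), 0)
  })
  K / rowSums(K)
}

# unit-variance correlated noise field via separably smoothed white noise
.smoothNoiseField <- function(nr, nc, radius) {
  eps <- matrix(stats::rnorm(nr * nc), nr, nc)
  f <- .smoothMatrix(nr, radius) %*% eps %*% t(.smoothMatrix(nc, radius))
  s <- stats::sd(as.vector(f))
  if (s > 0) f / s else f
}

#' Generate a synthetic basin-shaped DEM
#'
#' Elevation is the sum of a gentle west-east regional trend on the plateau,
#' a pocket-like depression at the basin center (full depth inside 0.8 x
#' radius, cosine-tapered to zero at 1.2 x radius) and a correlated noise
#' field (Gaussian-smoothed white noise scaled to \code{roughnessSd}).
#' The noise amplitude is damped to 45% on the basin floor — a pocket-like
#' area is a valley plain, smoother than the massif around it — so flat
#' cells, and with them high-VDC villages, cluster spatially inside the
#' basin. Deterministic given the config seed.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param seed RNG seed; defaults to \code{cfg@seed + 1} (the DEM stage).
#' @return a [DEMGrid-class].
#' @export
generateDEM <- function(cfg, seed = cfg@seed + 1L) {
  validObject(cfg)
  nr <- cfg@gridRows; nc <- cfg@gridCols
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  trend <- cfg@plateau -
    if (nc > 1) cfg@trendRange * (col - 1) / (nc - 1) else 0
  d <- sqrt((row - cfg@basinCenter[1])^2 + (col - cfg@basinCenter[2])^2)
  t <- pmin(1, pmax(0, (d / cfg@basinRadius - 0.8) / 0.4))
  depress <- cfg@basinDepth * (cos(pi * t) + 1) / 2
  noise <- if (cfg@roughnessSd > 0)
    cfg@roughnessSd * (0.45 + 0.55 * t) *
      .withSeed(seed, .smoothNoiseField(nr, nc, cfg@roughnessKernel))
  else 0
  DEMGrid(trend - depress + noise, cellSize = cfg@cellSize,
          origin = c(0, nr * cfg@cellSize))
}

#' Generate a Voronoi village tessellation
#'
#' Village polygons are the Voronoi cells of seed points clipped to the grid
#' rectangle: contiguous, non-overlapping, jointly covering the whole grid.
#' By default seeds are drawn without replacement from the DEM cell centers
#' and jittered by up to 0.3 cell in each axis: each seed stays nearest to
#' its own cell center (guaranteeing every village at least one member
#' cell) while cell boundaries stay in general position, off the lattice of
#' cell centers. Explicit seed coordinates can be supplied instead. Ids are
#' "V001", "V002", ... in seed order.
#'
#' @param dem the [DEMGrid-class] defining the extent.
#' @param cfg a [SyntheticConfig-class] (\code{nVillages} used).
#' @param seed RNG seed; defaults to \code{cfg@seed + 2} (village stage).
#' @param seedPoints optional n x 2 matrix of seed coordinates overriding the
#'   random draw.
#' @return a [VillageSet-class]; the seed coordinates are kept in the
#'   \code{"seeds"} attribute.
#' @export
generateVillages <- function(dem, cfg, seed = cfg@seed + 2L,
                             seedPoints = NULL) {
  nr <- nrow(dem@values); nc <- ncol(dem@values)
  n <- cfg@nVillages
  if (n < 4L) .configError("need at least 4 villages, got %d", n)
  if (n > nr * nc)
    .configError("nVillages (%d) exceeds the cell count (%d)", n, nr * nc)
  if (is.null(seedPoints)) {
    cc <- cellCenters(dem)
    seedPoints <- .withSeed(seed, {
      pick <- sample.int(nr * nc, n)
      jit <- matrix(stats::runif(2L * n, -0.3, 0.3), n, 2L) * dem@cellSize
      cbind(cc$x[pick], cc$y[pick]) + jit
    })
  } else {
    seedPoints <- as.matrix(seedPoints)
    if (nrow(seedPoints) != n)
      .configError("seedPoints rows (%d) must equal nVillages (%d)",
                   nrow(seedPoints), n)
  }
  cs <- dem@cellSize
  xmin <- dem@origin[1]; ymax <- dem@origin[2]
  cells <- .voronoiCells(seedPoints, xmin, xmin + nc * cs,
                         ymax - nr * cs, ymax)
  if (any(vapply(cells, nrow, integer(1)) < 3L))
    .dataError("degenerate Voronoi cell (duplicate seed points?)")
  vs <- villageSet(sprintf("V%03d", seq_len(n)), cells)
  attr(vs, "seeds") <- seedPoints
  vs
}

#' Generate a flatness-biased residential mask
#'
#' Marks a fraction of each village's cells as residential, sampled without
#' replacement with odds multiplied by \code{flatBias} for relatively flat
#' cells (3 x 3 focal range at or below 30 m) — people preferentially settle
#' flat ground. Every village receives at least one residential cell.
#'
#' @param dem the [DEMGrid-class].
#' @param villages a [VillageSet-class].
#' @param cfg a [SyntheticConfig-class] (resFraction, flatBias).
#' @param seed RNG seed; defaults to \code{cfg@seed + 3}.
#' @param flat optional precomputed flat mask from [extractRFA()].
#' @param membership optional matrix from [villageMembership()].
#' @return a [ResidentialMask-class].
#' @export
generateResidentialMask <- function(dem, villages, cfg,
                                    seed = cfg@seed + 3L, flat = NULL,
                                    membership = NULL) {
  if (is.null(flat)) flat <- extractRFA(focalRange(dem, 3L), 30)
  if (is.null(membership)) membership <- villageMembership(dem, villages)
  flatV <- as.vector(flat@values)
  memV <- as.vector(membership)
  mask <- numeric(length(memV))
  .withSeed(seed, {
    for (vi in seq_along(villages@ids)) {
      cand <- which(memV == vi)
      if (!length(cand))
        .dataError("village %s has no candidate cells for residences",
                   villages@ids[vi])
      k <- max(1L, round(cfg@resFraction * length(cand)))
      pr <- ifelse(flatV[cand] > 0, cfg@flatBias, 1)
      pick <- if (length(cand) == 1L) cand
              else cand[sample.int(length(cand), k, prob = pr)]
      mask[pick] <- 1
    }
  })
  ResidentialMask(matrix(mask, nrow(dem@values), ncol(dem@values)), dem)
}

#' Generate Poisson mortality from the terrain-driven risk surface
#'
#' Village populations are drawn uniformly from \code{popRange} (constant
#' across periods). The expected rate of village i is
#' \deqn{\lambda_i = baseline \times \exp(\beta_{VDC} (VDC_i - \overline{VDC})
#'   + \beta_{RDLS} (RDLS_i - \overline{RDLS}) + \eta_i)}
#' with \eqn{\eta} a spatially correlated Gaussian field (kernel range
#' \code{noiseRange}, sd \code{noiseSd}) shared across periods, so that the
#' risk surface — and its hotspots — persists over time. Covariates are
#' centered at their study means so \code{baselineRate} is the
#' typical-village rate. Deaths are Poisson per village-period. Villages
#' with zero population get zero deaths and an \code{excluded} flag.
#'
#' @param topo per-village terrain table with \code{village_id}, \code{VDC},
#'   \code{RDLS}, \code{x}, \code{y} (as from [zonalTopography()]).
#' @param cfg a [SyntheticConfig-class].
#' @param seed RNG seed; defaults to \code{cfg@seed + 4}.
#' @return list with \code{mortality} (long data.frame: village_id, period,
#'   deaths, population, excluded) and \code{truth} (expected rates per 1e5,
#'   the noise field and the generating slopes).
#' @export
generateMortality <- function(topo, cfg, seed = cfg@seed + 4L) {
  need <- c("village_id", "VDC", "RDLS", "x", "y")
  if (!all(need %in% names(topo)))
    .dataError("topography table needs columns: %s",
               paste(need, collapse = ", "))
  n <- nrow(topo)
  vdc <- topo$VDC
  vdc[is.na(vdc)] <- mean(vdc, na.rm = TRUE)
  rdls <- topo$RDLS
  .withSeed(seed, {
    pop <- if (cfg@popRange[1] == cfg@popRange[2]) rep(cfg@popRange[1], n)
           else sample(seq(cfg@popRange[1], cfg@popRange[2]), n,
                       replace = TRUE)
    eta <- rep(0, n)
    if (cfg@noiseSd > 0) {
      eps <- stats::rnorm(n)
      dmat <- as.matrix(stats::dist(cbind(topo$x, topo$y)))
      K <- exp(-0.5 * (dmat / cfg@noiseRange)^2)
      K <- K / rowSums(K)
      eta <- as.numeric(K %*% eps)
      s <- stats::sd(eta)
      if (s > 0) eta <- cfg@noiseSd * eta / s
    }
    lam <- cfg@baselineRate / 1e5 *
      exp(cfg@betaVdc * (vdc - mean(vdc)) +
          cfg@betaRdls * (rdls - mean(rdls)) + eta)
    rows <- vector("list", cfg@nPeriods)
    for (t in seq_len(cfg@nPeriods)) {
      deaths <- stats::rpois(n, pop * lam)
      deaths <- pmin(deaths, pop)
      rows[[t]] <- data.frame(village_id = topo$village_id,
                              period = sprintf("P%d", t),
                              deaths = deaths, population = pop,
                              excluded = pop == 0,
                              stringsAsFactors = FALSE)
    }
    mortality <- do.call(rbind, rows)
    mortality$deaths[mortality$excluded] <- 0L
    list(mortality = mortality,
         truth = list(village_id = topo$village_id,
                      expected_rate = lam * 1e5, eta = eta,
                      betaVdc = cfg@betaVdc, betaRdls = cfg@betaRdls,
                      baselineRate = cfg@baselineRate))
  })
}

#' Simulate a complete synthetic study
#'
#' Runs the generator stages in their fixed order — DEM, village
#' tessellation, flat-cell extraction, residential placement, zonal terrain
#' indices, mortality — each on its own seed offset from \code{cfg@seed}, so
#' the whole study is bit-reproducible from the config alone.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return a [SyntheticStudy-class].
#' @examples
#' study <- simulateStudy(syntheticConfig(gridRows = 40, gridCols = 40,
#'                                        nVillages = 25, seed = 7))
#' study
#' @export
simulateStudy <- function(cfg) {
  validObject(cfg)
  dem <- generateDEM(cfg)
  villages <- generateVillages(dem, cfg)
  flat <- extractRFA(focalRange(dem, 3L), 30)
  membership <- villageMembership(dem, villages)
  residential <- generateResidentialMask(dem, villages, cfg, flat = flat,
                                         membership = membership)
  topo <- zonalTopography(dem, flat, residential, villages,
                          membership = membership)
  mort <- generateMortality(topo, cfg)
  new("SyntheticStudy", dem = dem, villages = villages,
      residential = residential, topography = topo,
      mortality = mort$mortality, truth = mort$truth, config = cfg)
}

#' Write a synthetic study to disk
#'
#' Writes the pipeline input files: \code{dem.asc} and
#' \code{residential.asc} (ESRI ASCII grids), \code{villages.geojson},
#' \code{mortality.csv} and \code{config.yaml}.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
writeStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeAsciiGrid(study@dem, file.path(dir, "dem.asc"))
  writeAsciiGrid(study@residential, file.path(dir, "residential.asc"))
  writeVillagesGeoJSON(study@villages, file.path(dir, "villages.geojson"))
  writeMortalityCSV(study@mortality[, c("village_id", "period", "deaths",
                                        "population")],
                    file.path(dir, "mortality.csv"))
  cfg <- study@config
  cfgList <- sapply(slotNames(cfg), function(s) slot(cfg, s),
                    simplify = FALSE)
  yaml::write_yaml(cfgList, file.path(dir, "config.yaml"))
  invisible(dir)
}
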