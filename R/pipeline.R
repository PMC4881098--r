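# End-to-end orchestration: config handling, stage sequencing, table and
# GeoJSON outputs, run log.

# FNV-1a 32-bit hash of a character scalar (config fingerprint for the log).
# Arithmetic on 16-bit halves: R doubles lose bits at 2^32 * 2^24 and
# bitwXor() only accepts values below 2^31.
.fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b %% 256)
    hi <- bitwXor(h %/% 65536, b %/% 256)
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.defaultAnalysisConfig <- list(
  flat_threshold_m = 30, focal_window = 3L, BM = 500,
  contiguity = "queen", eb = TRUE, R0 = NULL,
  underreport_fraction = 0, permutations = 999L, seed = 1L,
  gwr_kernel = "bisquare", gwr_bounds = NULL, outdir = "."
)

#' Build or read an analysis configuration
#'
#' \code{analysisConfig} assembles and validates the configuration driving
#' [runPipeline()]; \code{readAnalysisConfig} loads one from a YAML file
#' (relative input paths are resolved against the file's directory).
#' Defaults mirror the study parameters: 30 m flatness threshold over a
#' 3 x 3 focal window, 500 m baseline-mountain height, queen contiguity,
#' spatial EB smoothing on, 999 permutations.
#'
#' @param dem,villages,residential,mortality input paths (DEM and
#'   residential mask as ESRI ASCII grids — residential alternatively as a
#'   GeoJSON polygon layer rasterized by the cell-center rule; villages as
#'   GeoJSON; mortality as CSV).
#' @param R0 reference rate per 1e5 for the five-level categories
#'   (required).
#' @param ... overrides of the defaults listed above.
#' @return a validated named list (class "topomort_config").
#' @export
analysisConfig <- function(dem, villages, residential, mortality, R0, ...) {
  cfg <- utils::modifyList(.defaultAnalysisConfig, list(...))
  cfg$dem <- dem; cfg$villages <- villages
  cfg$residential <- residential; cfg$mortality <- mortality
  cfg$R0 <- R0
  .validateAnalysisConfig(cfg)
}

#' @param path YAML config path.
#' @rdname analysisConfig
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) .configError("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  cfg <- utils::modifyList(.defaultAnalysisConfig, raw)
  base <- dirname(normalizePath(path))
  for (k in c("dem", "villages", "residential", "mortality")) {
    if (!is.null(cfg[[k]]) && !grepl("^(/|[A-Za-z]:)", cfg[[k]]))
      cfg[[k]] <- file.path(base, cfg[[k]])
  }
  .validateAnalysisConfig(cfg)
}

.validateAnalysisConfig <- function(cfg) {
  for (k in c("dem", "villages", "residential", "mortality")) {
    if (is.null(cfg[[k]]))
      .configError("config is missing the '%s' input path", k)
    if (!file.exists(cfg[[k]]))
      .configError("input file for '%s' not found: %s", k, cfg[[k]])
  }
  if (is.null(cfg$R0) || !is.numeric(cfg$R0) || cfg$R0 <= 0)
    .configError("config must set a positive reference rate R0 (per 1e5)")
  if (!cfg$contiguity %in% c("queen", "rook"))
    .configError("contiguity must be 'queen' or 'rook'")
  if (cfg$flat_threshold_m < 0)
    .configError("flat_threshold_m must be non-negative")
  if (any(cfg$underreport_fraction < 0) || any(cfg$underreport_fraction >= 1))
    .configError("underreport_fraction must lie in [0, 1)")
  class(cfg) <- c("topomort_config", "list")
  cfg
}

.readResidential <- function(path, dem) {
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    polys <- readVillagesGeoJSON(path)
    cc <- cellCenters(dem)
    inside <- rep(FALSE, nrow(cc))
    for (p in polys@polygons)
      inside <- inside | .pointsInPolygon(cc$x, cc$y, p)
    ResidentialMask(matrix(as.numeric(inside), nrow(dem@values),
                           ncol(dem@values)), dem)
  } else {
    g <- readAsciiGrid(path)
    if (!all(dim(g@values) == dim(dem@values)) ||
        g@cellSize != dem@cellSize || any(g@origin != dem@origin))
      .dataError("residential raster is not aligned with the DEM grid")
    m <- g@values
    m[is.na(m)] <- 0
    ResidentialMask(m, g)
  }
}

.summaryRow <- function(x, label) {
  x <- x[is.finite(x)]
  data.frame(attribute = label, mean = mean(x), range = diff(range(x)),
             sd = stats::sd(x), n = length(x), stringsAsFactors = FALSE)
}

#' Run the full mortality-topography pipeline
#'
#' Executes the stages in order — terrain indices, rate smoothing and
#' categorization, spatial clustering, mortality-terrain association — and
#' writes per-stage outputs under \code{config$outdir}:
#' \itemize{
#'   \item \code{village_topography.csv} — per-village terrain table;
#'   \item \code{mortality_rates.csv} — crude/smoothed rates and categories;
#'   \item \code{summary_table.csv} — mean/range/SD per attribute per period;
#'   \item \code{moran_table.csv} — Moran's I, z, p per attribute/period;
#'   \item \code{gistar_<period>.csv} and \code{hotspots_<period>.geojson} —
#'     local Gi* and hotspot classes;
#'   \item \code{persistent_hotspots.csv} — villages hot in every period;
#'   \item \code{correlation_table.csv} — rate~RDLS, rate~VDC, RDLS~VDC;
#'   \item \code{gwr_comparison.csv} — AICc-ranked model variants per period;
#'   \item \code{run_log.txt} — config hash, seed, stage trace.
#' }
#' All randomness (Moran permutations) derives from \code{config$seed}, so
#' repeated runs produce byte-identical tables.
#'
#' @param config list from [analysisConfig()] or [readAnalysisConfig()].
#' @param upTo last stage to execute: "terrain", "rates", "clustering" or
#'   "association" (default, the full pipeline). Earlier stages always run —
#'   later ones need their outputs.
#' @return invisibly, a list with every table produced.
#' @export
runPipeline <- function(config, upTo = c("association", "clustering",
                                         "rates", "terrain")) {
  upTo <- match.arg(upTo)
  depth <- match(upTo, c("terrain", "rates", "clustering", "association"))
  config <- .validateAnalysisConfig(config)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logLines <- c(sprintf("topomort run, config hash %s, seed %d",
                        .fnv1a(paste(deparse(config), collapse = "")),
                        as.integer(config$seed)))
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    logLines <<- c(logLines, msg)
  }

  stage <- function(name, expr) {
    # abort with the stage name while preserving the condition class, so
    # callers can still distinguish config/data/numerical failures
    tryCatch(expr, error = function(e) {
      stop(structure(class = unique(c(class(e), "error", "condition")),
                     list(message = sprintf("pipeline stage '%s' failed: %s",
                                            name, conditionMessage(e)),
                          call = conditionCall(e))))
    })
  }

  # --- inputs -------------------------------------------------------------
  dem <- stage("inputs", readAsciiGrid(config$dem))
  villages <- stage("inputs", readVillagesGeoJSON(config$villages))
  residential <- stage("inputs", .readResidential(config$residential, dem))
  mortality <- stage("inputs", readMortalityCSV(config$mortality))
  say("inputs: %d x %d DEM, %d villages, %d mortality rows",
      nrow(dem@values), ncol(dem@values), length(villages), nrow(mortality))

  # --- terrain ------------------------------------------------------------
  topo <- stage("terrain", {
    flat <- extractRFA(focalRange(dem, config$focal_window),
                       config$flat_threshold_m)
    zonalTopography(dem, flat, residential, villages, BM = config$BM)
  })
  say("terrain: %d villages with cells; mean RDLS %.2f, mean VDC %.2f",
      nrow(topo), mean(topo$RDLS), mean(topo$VDC, na.rm = TRUE))

  wr <- function(df, f) utils::write.csv(df, file.path(outdir, f),
                                         row.names = FALSE)
  finish <- function(results) {
    writeLines(logLines, file.path(outdir, "run_log.txt"))
    invisible(results)
  }
  wr(topo, "village_topography.csv")
  if (depth == 1L) return(finish(list(topography = topo)))

  # --- weights ------------------------------------------------------------
  W <- stage("weights", buildContiguityWeights(villages, config$contiguity))

  # --- rates --------------------------------------------------------------
  periods <- sort(unique(mortality$period))
  rateTables <- stage("rates", {
    lapply(periods, function(pd) {
      tb <- mortality[mortality$period == pd,
                      c("village_id", "period", "deaths", "population")]
      tb <- tb[tb$village_id %in% topo$village_id, , drop = FALSE]
      tb$deaths <- adjustUnderreporting(tb$deaths,
                                        config$underreport_fraction)
      tb <- if (isTRUE(config$eb)) spatialEBSmooth(tb, W)
            else { tb <- crudeRates(tb); tb$smoothed_rate <- tb$crude_rate; tb }
      tb$category <- categorizeRates(tb$smoothed_rate, config$R0)
      tb
    })
  })
  names(rateTables) <- periods
  rateTable <- do.call(rbind, rateTables)
  say("rates: %d periods, smoothed with EB = %s", length(periods),
      isTRUE(config$eb))

  # --- summary (per-attribute descriptive statistics) ----------------------
  summaryTable <- do.call(rbind, c(
    lapply(periods, function(pd)
      .summaryRow(rateTables[[pd]]$smoothed_rate,
                  sprintf("smoothed_rate_%s", pd))),
    list(.summaryRow(topo$RDLS, "RDLS"), .summaryRow(topo$VDC, "VDC"))
  ))
  wr(rateTable, "mortality_rates.csv")
  wr(summaryTable, "summary_table.csv")
  if (depth == 2L)
    return(finish(list(topography = topo, rates = rateTable,
                       summary = summaryTable, weights = W)))

  # --- clustering ----------------------------------------------------------
  moranRows <- list(); giTables <- list()
  stage("clustering", {
    for (pd in periods) {
      tb <- rateTables[[pd]]
      ok <- !tb$excluded & is.finite(tb$smoothed_rate)
      Wp <- subsetWeights(W, tb$village_id[ok])
      mt <- moransITest(tb$smoothed_rate[ok], Wp, method = "permutation",
                        nPerm = config$permutations, seed = config$seed)
      ma <- moransITest(tb$smoothed_rate[ok], Wp, method = "analytic")
      moranRows[[length(moranRows) + 1L]] <- data.frame(
        attribute = sprintf("smoothed_rate_%s", pd), I = mt@I,
        z_perm = mt@zScore, p_perm = mt@pValue,
        z_analytic = ma@zScore, p_analytic = ma@pValue, n = mt@n)
      giTables[[pd]] <- giStar(tb$smoothed_rate[ok], Wp)
    }
    for (attr in c("RDLS", "VDC")) {
      x <- topo[[attr]]
      ok <- is.finite(x)
      Wa <- subsetWeights(W, topo$village_id[ok])
      mt <- moransITest(x[ok], Wa, method = "permutation",
                        nPerm = config$permutations, seed = config$seed)
      ma <- moransITest(x[ok], Wa, method = "analytic")
      moranRows[[length(moranRows) + 1L]] <- data.frame(
        attribute = attr, I = mt@I, z_perm = mt@zScore, p_perm = mt@pValue,
        z_analytic = ma@zScore, p_analytic = ma@pValue, n = mt@n)
    }
  })
  moranTable <- do.call(rbind, moranRows)
  persistent <- if (length(periods) >= 2L &&
                    length(unique(lapply(giTables, function(t)
                      sort(t$village_id)))) == 1L)
    persistentHotspots(giTables) else character(0)
  say("clustering: Moran's I on %d attributes; %d persistent hotspots",
      nrow(moranTable), length(persistent))
  wr(moranTable, "moran_table.csv")
  for (pd in periods) {
    wr(giTables[[pd]], sprintf("gistar_%s.csv", pd))
    keep <- villages@ids %in% giTables[[pd]]$village_id
    sub <- villageSet(villages@ids[keep], villages@polygons[keep])
    writeVillagesGeoJSON(sub,
                         file.path(outdir, sprintf("hotspots_%s.geojson", pd)),
                         properties = giTables[[pd]])
  }
  wr(data.frame(village_id = persistent), "persistent_hotspots.csv")
  if (depth == 3L)
    return(finish(list(topography = topo, rates = rateTable,
                       summary = summaryTable, moran = moranTable,
                       gistar = giTables, persistent_hotspots = persistent,
                       weights = W)))

  # --- association ----------------------------------------------------------
  corRows <- list(); gwrRows <- list()
  stage("association", {
    ti <- match(rateTable$village_id, topo$village_id)
    rateTable$RDLS <- topo$RDLS[ti]
    rateTable$VDC <- topo$VDC[ti]
    for (pd in periods) {
      tb <- rateTable[rateTable$period == pd, ]
      ok <- is.finite(tb$smoothed_rate)
      corRows[[length(corRows) + 1L]] <- cbind(period = pd,
        pearsonCorrelation(tb$smoothed_rate[ok], tb$RDLS[ok], "rate~RDLS"))
      okv <- ok & is.finite(tb$VDC)
      corRows[[length(corRows) + 1L]] <- cbind(period = pd,
        pearsonCorrelation(tb$smoothed_rate[okv], tb$VDC[okv], "rate~VDC"))
    }
    okt <- is.finite(topo$RDLS) & is.finite(topo$VDC)
    corRows[[length(corRows) + 1L]] <- cbind(period = "all",
      pearsonCorrelation(topo$RDLS[okt], topo$VDC[okt], "RDLS~VDC"))
    for (pd in periods) {
      tb <- rateTable[rateTable$period == pd, ]
      ok <- is.finite(tb$smoothed_rate) & is.finite(tb$VDC) &
        is.finite(tb$RDLS)
      tb <- tb[ok, ]
      xy <- centroids(villages)
      ci <- match(tb$village_id, xy$village_id)
      cmp <- compareGWRModels(tb$smoothed_rate,
                              tb[, c("RDLS", "VDC")],
                              cbind(xy$x[ci], xy$y[ci]),
                              kernel = config$gwr_kernel,
                              bounds = config$gwr_bounds)
      fits <- attr(cmp, "fits")
      cmp$stdres_cover <- vapply(cmp$variant, function(v)
        stdresidCoverage(fits[[v]]), numeric(1))
      gwrRows[[length(gwrRows) + 1L]] <- cbind(period = pd, cmp)
    }
  })
  corTable <- do.call(rbind, corRows)
  gwrTable <- do.call(rbind, gwrRows)
  say("association: %d correlations, %d GWR fits", nrow(corTable),
      nrow(gwrTable))

  # --- outputs ----------------------------------------------------------------
  wr(corTable, "correlation_table.csv")
  wr(gwrTable, "gwr_comparison.csv")
  finish(list(topography = topo, rates = rateTable,
              summary = summaryTable, moran = moranTable,
              gistar = giTables, persistent_hotspots = persistent,
              correlations = corTable, gwr = gwrTable, weights = W))
}
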