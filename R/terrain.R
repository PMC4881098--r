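#' Focal elevation range
#'
#' Per-cell difference between the maximum and minimum elevation in the
#' surrounding \code{window} x \code{window} neighborhood (default 3 x 3, the
#' neighborhood used to delimit relatively flat areas). At the grid border
#' the window shrinks to the available cells; nodata cells are excluded, and
#' a cell whose whole window is nodata yields nodata.
#'
#' @param dem a [DEMGrid-class].
#' @param window odd window edge length in cells (>= 3).
#' @return a [DEMGrid-class] of ranges (m) with the same geometry.
#' @seealso [extractRFA()]
#' @export
focalRange <- function(dem, window = 3L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    .configError("focal window must be an odd integer >= 3, got %d", window)
  v <- dem@values
  nr <- nrow(v); nc <- ncol(v)
  half <- window %/% 2L
  hi <- matrix(NA_real_, nr, nc)
  lo <- matrix(NA_real_, nr, nc)
  for (di in -half:half) {
    rs <- seq_len(nr) + di
    ok_r <- rs >= 1L & rs <= nr
    for (dj in -half:half) {
      cs <- seq_len(nc) + dj
      ok_c <- cs >= 1L & cs <= nc
      sh <- matrix(NA_real_, nr, nc)
      sh[ok_r, ok_c] <- v[rs[ok_r], cs[ok_c]]
      hi <- pmax(hi, sh, na.rm = TRUE)
      lo <- pmin(lo, sh, na.rm = TRUE)
    }
  }
  out <- hi - lo
  DEMGrid(out, cellSize = dem@cellSize, origin = dem@origin,
          nodata = dem@nodata, crs = dem@crs)
}

#' Relatively flat areas from a focal-range raster
#'
#' Flags cells whose neighborhood elevation range is less than or equal to
#' \code{threshold} (default 30 m, boundary inclusive). Nodata cells are
#' never flat.
#'
#' @param rangeRaster a [DEMGrid-class] of focal ranges, from [focalRange()].
#' @param threshold flatness threshold in meters (>= 0).
#' @return a [ResidentialMask-class]-like binary [DEMGrid-class] (1 = flat).
#' @export
extractRFA <- function(rangeRaster, threshold = 30) {
  if (length(threshold) != 1L || !is.finite(threshold) || threshold < 0)
    .configError("flatness threshold must be a single non-negative number")
  v <- rangeRaster@values
  flat <- ifelse(is.na(v), 0, as.numeric(v <= threshold))
  DEMGrid(flat, cellSize = rangeRaster@cellSize, origin = rangeRaster@origin,
          nodata = rangeRaster@nodata, crs = rangeRaster@crs)
}

#' Assign DEM cells to villages
#'
#' A cell belongs to the village whose polygon contains its center; cells on
#' a shared boundary go to the first containing village in id order. Returns
#' an integer matrix of village indices (NA = no village).
#'
#' @param dem a [DEMGrid-class].
#' @param villages a [VillageSet-class].
#' @return integer matrix shaped like the DEM.
#' @export
villageMembership <- function(dem, villages) {
  cc <- cellCenters(dem)
  member <- rep(NA_integer_, nrow(cc))
  ord <- order(villages@ids)
  for (vi in ord) {
    poly <- villages@polygons[[vi]]
    bb <- .bbox(poly)
    cand <- which(is.na(member) &
                  cc$x >= bb[1] & cc$x <= bb[3] &
                  cc$y >= bb[2] & cc$y <= bb[4])
    if (!length(cand)) next
    hit <- .pointsInPolygon(cc$x[cand], cc$y[cand], poly)
    member[cand[hit]] <- vi
  }
  matrix(member, nrow = nrow(dem@values), ncol = ncol(dem@values))
}

#' Per-village zonal terrain statistics
#'
#' Computes, for every village, the zonal quantities behind the terrain
#' indices: mean altitude ALT (m), altitude range RangeH (m), area A (km2,
#' cell count x cell area), flat area PA, residential area VRA and flat
#' residential area VRAf (all km2), then the dwelling-condition index
#' VDC = VRAf / VRA and the land-surface relief
#' RDLS = ALT/1000 + RangeH x (1 - PA/A) / BM.
#'
#' Villages containing no cell centers are dropped with a warning naming
#' them. Villages without residential cells keep \code{VDC = NA} and are
#' flagged in \code{vdc_defined}.
#'
#' @param dem a [DEMGrid-class].
#' @param flatMask binary flat-cell raster from [extractRFA()].
#' @param residential a [ResidentialMask-class] (or binary [DEMGrid-class]).
#' @param villages a [VillageSet-class].
#' @param BM baseline-mountain height in meters (default 500).
#' @param membership optional precomputed matrix from [villageMembership()].
#' @return data.frame with one row per retained village: village_id, n_cells,
#'   ALT, RangeH, A, PA, VRA, VRAf, VDC, RDLS, vdc_defined, and centroid
#'   coordinates x, y.
#' @export
zonalTopography <- function(dem, flatMask, residential, villages, BM = 500,
                            membership = NULL) {
  for (r in list(flatMask, residential)) {
    if (!all(dim(r@values) == dim(dem@values)))
      .dataError("rasters are not aligned with the DEM")
  }
  if (is.null(membership)) membership <- villageMembership(dem, villages)
  idx <- as.vector(membership)
  keep <- !is.na(idx)
  idx <- idx[keep]
  elev <- as.vector(dem@values)[keep]
  flat <- as.vector(flatMask@values)[keep]
  res <- as.vector(residential@values)[keep]
  flat[is.na(flat)] <- 0
  res[is.na(res)] <- 0

  n <- length(villages@ids)
  f <- factor(idx, levels = seq_len(n))
  nCells <- as.integer(table(f))
  empty <- nCells == 0L
  if (any(empty))
    warning("villages with no DEM cells excluded: ",
            paste(villages@ids[empty], collapse = ", "))

  cellKm2 <- (dem@cellSize / 1000)^2
  alt <- tapply(elev, f, mean, na.rm = TRUE)
  hmax <- tapply(elev, f, function(z) suppressWarnings(max(z, na.rm = TRUE)))
  hmin <- tapply(elev, f, function(z) suppressWarnings(min(z, na.rm = TRUE)))
  pa <- tapply(flat, f, sum)
  vra <- tapply(res, f, sum)
  vraf <- tapply(flat * res, f, sum)
  ctr <- centroids(villages)

  out <- data.frame(
    village_id = villages@ids,
    n_cells = nCells,
    ALT = as.numeric(alt),
    RangeH = as.numeric(hmax) - as.numeric(hmin),
    A = nCells * cellKm2,
    PA = as.numeric(pa) * cellKm2,
    VRA = as.numeric(vra) * cellKm2,
    VRAf = as.numeric(vraf) * cellKm2,
    x = ctr$x, y = ctr$y,
    stringsAsFactors = FALSE
  )
  out <- out[!empty, , drop = FALSE]
  out$VDC <- computeVDC(out$VRAf, out$VRA)
  out$vdc_defined <- out$VRA > 0
  out$RDLS <- computeRDLS(out$ALT, out$RangeH, out$A, out$PA, BM = BM)
  rownames(out) <- NULL
  out
}

#' Village dwelling condition (VDC)
#'
#' Fraction of a village's residential area lying in relatively flat terrain:
#' \code{VDC = VRAf / VRA}, in [0, 1]. A village without residential area
#' (VRA = 0) has an undefined VDC and is returned as \code{NA}.
#'
#' @param VRAf flat residential area (km2).
#' @param VRA total residential area (km2).
#' @return numeric vector of VDC values.
#' @examples
#' computeVDC(79.98, 164.88)   # city-level aggregate, ~0.49
#' @export
computeVDC <- function(VRAf, VRA) {
  if (any(VRA < 0) || any(VRAf < 0))
    .dataError("residential areas must be non-negative")
  if (any(VRAf > VRA + 1e-9))
    .dataError("flat residential area exceeds total residential area")
  ifelse(VRA > 0, VRAf / VRA, NA_real_)
}

#' Relief degree of land surface (RDLS)
#'
#' Composite terrain index combining mean altitude, elevation range and the
#' non-flat fraction of a zone:
#' \deqn{RDLS = ALT/1000 + RangeH \times (1 - PA/A) / BM}
#' with ALT and RangeH in meters, areas in km2 and BM the baseline-mountain
#' height (500 m by convention for mainland China). The first term converts
#' mean altitude to km; the lower bound ALT/1000 is attained exactly when the
#' zone has no relief (RangeH = 0) or is entirely flat (PA = A).
#'
#' @param ALT mean altitude (m).
#' @param RangeH max - min altitude (m).
#' @param A zone area (km2), > 0.
#' @param PA flat area within the zone (km2), 0 <= PA <= A.
#' @param BM baseline-mountain height (m), > 0.
#' @return numeric vector of RDLS values.
#' @examples
#' computeRDLS(ALT = 2000, RangeH = 500, A = 10, PA = 2.5)  # 2.75
#' @export
computeRDLS <- function(ALT, RangeH, A, PA, BM = 500) {
  if (any(BM <= 0)) .configError("BM must be positive")
  if (any(A <= 0)) .dataError("village area must be positive")
  if (any(PA < -1e-9) || any(PA > A + 1e-9))
    .dataError("flat area must satisfy 0 <= PA <= A")
  if (any(RangeH < 0)) .dataError("elevation range cannot be negative")
  ALT / 1000 + RangeH * (1 - PA / A) / BM
}
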