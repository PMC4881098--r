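#' @include AllClasses.R
NULL

#' Accessors for raster and vector containers
#'
#' \code{gridValues} returns the value matrix of a [DEMGrid-class] (row 1 =
#' north); \code{cellSize} its cell edge in meters; \code{gridOrigin} the
#' top-left corner; \code{cellCenters} a data.frame of cell-center map
#' coordinates. \code{villageIds}, \code{polygons}, \code{villageAreas} and
#' \code{centroids} access a [VillageSet-class]; \code{weightsMatrix} the
#' binary matrix of a [SpatialWeights-class].
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname accessors
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname accessors
#' @export
setGeneric("villageIds", function(x) standardGeneric("villageIds"))

#' @rdname accessors
#' @export
setGeneric("polygons", function(x) standardGeneric("polygons"))

#' @rdname accessors
#' @export
setGeneric("villageAreas", function(x) standardGeneric("villageAreas"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("weightsMatrix", function(x) standardGeneric("weightsMatrix"))

setMethod("gridValues", "DEMGrid", function(x) x@values)
setMethod("cellSize", "DEMGrid", function(x) x@cellSize)
setMethod("gridOrigin", "DEMGrid", function(x) x@origin)

setMethod("cellCenters", "DEMGrid", function(x) {
  nr <- nrow(x@values); nc <- ncol(x@values); cs <- x@cellSize
  col <- rep(seq_len(nc), each = nr)
  row <- rep(seq_len(nr), times = nc)
  data.frame(row = row, col = col,
             x = x@origin[1] + (col - 0.5) * cs,
             y = x@origin[2] - (row - 0.5) * cs)
})

#' @export
setMethod("dim", "DEMGrid", function(x) dim(x@values))

setMethod("villageIds", "VillageSet", function(x) x@ids)
setMethod("polygons", "VillageSet", function(x) x@polygons)
setMethod("villageAreas", "VillageSet", function(x) x@areas)

setMethod("centroids", "VillageSet", function(x) {
  xy <- t(vapply(x@polygons, .polygonCentroid, numeric(2)))
  data.frame(village_id = x@ids, x = xy[, 1], y = xy[, 2])
})

#' @export
setMethod("length", "VillageSet", function(x) length(x@ids))

setMethod("villageIds", "SpatialWeights", function(x) x@ids)
setMethod("weightsMatrix", "SpatialWeights", function(x) x@w)

#' @export
setMethod("show", "DEMGrid", function(object) {
  v <- object@values
  cat(sprintf("%s: %d x %d cells of %g m\n", class(object),
              nrow(v), ncol(v), object@cellSize))
  if (length(v)) {
    r <- range(v, na.rm = TRUE)
    cat(sprintf("  values: %.1f .. %.1f (%d nodata)\n", r[1], r[2],
                sum(is.na(v))))
  }
  cat(sprintf("  origin (top-left): %g, %g; CRS: %s\n",
              object@origin[1], object@origin[2], object@crs))
})

#' @export
setMethod("show", "VillageSet", function(object) {
  cat(sprintf("VillageSet: %d villages, total area %.2f km2\n",
              length(object@ids), sum(object@areas)))
})

#' @export
setMethod("show", "SpatialWeights", function(object) {
  nn <- rowSums(object@w) - as.integer(object@includeSelf)
  cat(sprintf("SpatialWeights (%s%s): %d villages, mean %.2f neighbors\n",
              object@rule, if (object@includeSelf) ", self included" else "",
              length(object@ids), mean(nn)))
  if (any(nn == 0))
    cat(sprintf("  %d island(s) with no neighbors\n", sum(nn == 0)))
})

#' @export
setMethod("show", "MoranResult", function(object) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), z = %.3f, p = %.4g [%s%s]\n",
              object@I, object@expectation, object@zScore, object@pValue,
              object@method,
              if (object@method == "permutation")
                sprintf(", %d perms", object@nPerm) else ""))
})

#' @export
setMethod("show", "GWRResult", function(object) {
  cat(sprintf("GWR fit: %d locations, kernel %s (%s bandwidth %g)\n",
              nrow(object@localCoef), object@kernel,
              if (object@adaptive) "adaptive" else "fixed", object@bandwidth))
  cat(sprintf("  R2 = %.4f, adj. R2 = %.4f, AICc = %.2f, eff. params = %.2f\n",
              object@R2, object@adjR2, object@AICc, object@v1))
})

#' @export
setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy: %d villages, %d periods, seed %d\n",
              length(object@villages), object@config@nPeriods,
              object@config@seed))
})
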