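#' Build binary contiguity weights from village polygons
#'
#' Two villages are contiguous under the queen rule when their polygon
#' boundaries share at least one point, and under the rook rule when they
#' share a boundary segment of positive length. The matrix is binary and
#' symmetric (never row-standardized); islands (villages with no neighbor)
#' are allowed with a warning. With \code{includeSelf = TRUE} the diagonal is
#' set to 1 (the Gi* convention).
#'
#' @param villages a [VillageSet-class].
#' @param rule "queen" (default, any shared boundary point) or "rook"
#'   (shared edge of positive length).
#' @param includeSelf put 1 on the diagonal.
#' @param snap distance tolerance (map units) under which boundaries are
#'   considered touching; defaults to 1e-6 of the study diameter.
#' @return a [SpatialWeights-class].
#' @examples
#' sq <- function(x0, y0) cbind(c(x0, x0 + 1, x0 + 1, x0), c(y0, y0, y0 + 1, y0 + 1)) * 1000
#' vs <- villageSet(c("a", "b", "c", "d"),
#'                  list(sq(0, 0), sq(1, 0), sq(0, 1), sq(1, 1)))
#' rowSums(weightsMatrix(buildContiguityWeights(vs, "rook")))   # 2 2 2 2
#' rowSums(weightsMatrix(buildContiguityWeights(vs, "queen")))  # 3 3 3 3
#' @export
buildContiguityWeights <- function(villages, rule = c("queen", "rook"),
                                   includeSelf = FALSE, snap = NULL) {
  rule <- match.arg(rule)
  ids <- villages@ids
  if (anyDuplicated(ids)) .dataError("duplicate village ids")
  n <- length(ids)
  polys <- villages@polygons
  bbs <- t(vapply(polys, .bbox, numeric(4)))
  if (is.null(snap)) {
    diam <- sqrt((max(bbs[, 3]) - min(bbs[, 1]))^2 +
                 (max(bbs[, 4]) - min(bbs[, 2]))^2)
    snap <- 1e-6 * max(diam, 1)
  }
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    # bounding-box prefilter: boxes must come within snap of each other
    js <- which(bbs[, 1] <= bbs[i, 3] + snap & bbs[, 3] >= bbs[i, 1] - snap &
                bbs[, 2] <= bbs[i, 4] + snap & bbs[, 4] >= bbs[i, 2] - snap)
    js <- js[js > i]
    for (j in js) {
      touch <- if (rule == "queen") {
        .polyBoundaryDist(polys[[i]], polys[[j]]) <= snap
      } else {
        .sharedBoundaryLength(polys[[i]], polys[[j]], snap) > snap
      }
      if (touch) w[i, j] <- w[j, i] <- 1
    }
  }
  if (n > 1 && any(rowSums(w) == 0))
    warning("island villages with no neighbors: ",
            paste(ids[rowSums(w) == 0], collapse = ", "))
  if (includeSelf) diag(w) <- 1
  new("SpatialWeights", ids = ids, w = w, rule = rule,
      includeSelf = includeSelf)
}

#' Reorder or subset a weights matrix to a set of ids
#'
#' @param W a [SpatialWeights-class].
#' @param ids village ids to keep, in the desired order.
#' @return a [SpatialWeights-class] over \code{ids}.
#' @export
subsetWeights <- function(W, ids) {
  pos <- match(as.character(ids), W@ids)
  if (any(is.na(pos)))
    .dataError("ids absent from the weights: %s",
               paste(ids[is.na(pos)], collapse = ", "))
  new("SpatialWeights", ids = as.character(ids),
      w = W@w[pos, pos, drop = FALSE], rule = W@rule,
      includeSelf = W@includeSelf)
}
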