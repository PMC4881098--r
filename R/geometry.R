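# Computational-geometry internals: polygon measures, point-in-polygon,
# half-plane clipping, bounded Voronoi diagrams and segment distances.
# All coordinates are in the projected map units (meters).

# classed conditions so the CLI can map error kinds to exit codes
.configError <- function(...) {
  stop(structure(class = c("topomort_config_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}
.dataError <- function(...) {
  stop(structure(class = c("topomort_data_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}
.numError <- function(...) {
  stop(structure(class = c("topomort_numeric_error", "error", "condition"),
                 list(message = sprintf(...), call = sys.call(-1))))
}

# signed shoelace area; vertices need not repeat the first point
.polygonSignedArea <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

.polygonArea <- function(xy) abs(.polygonSignedArea(xy))

.polygonCentroid <- function(xy) {
  a <- .polygonSignedArea(xy)
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  cr <- x[j] * y - x * y[j]
  c(sum((x[j] + x) * cr), sum((y[j] + y) * cr)) / (6 * a)
}

# ray-casting test, vectorized over points; boundary points may fall either
# way (membership ties are resolved by assignment order, see .villageMembership)
.pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

# Sutherland-Hodgman clip of a convex polygon by half-plane a*x + b*y <= c
.clipHalfPlane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - cc
  if (all(d <= 0)) return(poly)
  if (all(d > 0)) return(poly[0, , drop = FALSE])
  out <- matrix(0, n + 4L, 2L)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) {
      k <- k + 1L; out[k, ] <- poly[i, ]
    }
    if ((di <= 0) != (dj <= 0)) {
      t <- di / (di - dj)
      k <- k + 1L
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Voronoi cells of seed points clipped to the rectangle [xmin,xmax]x[ymin,ymax].
# Each cell is built by clipping the rectangle with the perpendicular-bisector
# half-planes against other seeds, nearest first; a seed j whose half distance
# exceeds the cell's current circumradius cannot cut and terminates the scan.
.voronoiCells <- function(seeds, xmin, xmax, ymin, ymax) {
  n <- nrow(seeds)
  rect <- matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
                 ncol = 2, byrow = TRUE)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    si <- seeds[i, ]
    d2 <- (seeds[, 1] - si[1])^2 + (seeds[, 2] - si[2])^2
    ord <- order(d2)
    ord <- ord[d2[ord] > 0]
    poly <- rect
    maxR2 <- max((poly[, 1] - si[1])^2 + (poly[, 2] - si[2])^2)
    for (j in ord) {
      if (d2[j] / 4 > maxR2) break
      sj <- seeds[j, ]
      a <- sj[1] - si[1]; b <- sj[2] - si[2]
      m <- (si + sj) / 2
      poly <- .clipHalfPlane(poly, a, b, a * m[1] + b * m[2])
      if (nrow(poly) == 0L) break
      maxR2 <- max((poly[, 1] - si[1])^2 + (poly[, 2] - si[2])^2)
    }
    cells[[i]] <- poly
  }
  cells
}

# squared distance from points (px,py) to segment p1-p2
.pointSegDist2 <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return((px - x1)^2 + (py - y1)^2)
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
}

# minimum distance between every edge of poly A and every edge of poly B;
# returns the global minimum. Vectorized over A's vertices per B-edge.
.polyBoundaryDist <- function(pa, pb) {
  na <- nrow(pa); nb <- nrow(pb)
  ia2 <- c(seq_len(na)[-1], 1L)
  ib2 <- c(seq_len(nb)[-1], 1L)
  best <- Inf
  for (k in seq_len(nb)) {
    d <- .pointSegDist2(pa[, 1], pa[, 2],
                        pb[k, 1], pb[k, 2], pb[ib2[k], 1], pb[ib2[k], 2])
    best <- min(best, min(d))
  }
  for (k in seq_len(na)) {
    d <- .pointSegDist2(pb[, 1], pb[, 2],
                        pa[k, 1], pa[k, 2], pa[ia2[k], 1], pa[ia2[k], 2])
    best <- min(best, min(d))
  }
  # segment interiors crossing without close vertices cannot occur for
  # non-overlapping polygons, so vertex-to-edge distances suffice
  sqrt(best)
}

# total length along which the boundaries of two polygons run together
# (within tolerance tol): the rook-contiguity criterion.
.sharedBoundaryLength <- function(pa, pb, tol) {
  na <- nrow(pa); nb <- nrow(pb)
  ia2 <- c(seq_len(na)[-1], 1L)
  ib2 <- c(seq_len(nb)[-1], 1L)
  total <- 0
  for (i in seq_len(na)) {
    a1 <- pa[i, ]; a2 <- pa[ia2[i], ]
    va <- a2 - a1
    La <- sqrt(sum(va^2))
    if (La < tol) next
    ua <- va / La
    for (j in seq_len(nb)) {
      b1 <- pb[j, ]; b2 <- pb[ib2[j], ]
      # both endpoints of B's edge must lie on A's supporting line
      off1 <- abs((b1[1] - a1[1]) * ua[2] - (b1[2] - a1[2]) * ua[1])
      off2 <- abs((b2[1] - a1[1]) * ua[2] - (b2[2] - a1[2]) * ua[1])
      if (off1 > tol || off2 > tol) next
      t1 <- (b1[1] - a1[1]) * ua[1] + (b1[2] - a1[2]) * ua[2]
      t2 <- (b2[1] - a1[1]) * ua[1] + (b2[2] - a1[2]) * ua[2]
      lo <- max(0, min(t1, t2)); hi <- min(La, max(t1, t2))
      if (hi > lo) total <- total + (hi - lo)
    }
  }
  total
}

.bbox <- function(poly) c(min(poly[, 1]), min(poly[, 2]),
                          max(poly[, 1]), max(poly[, 2]))
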