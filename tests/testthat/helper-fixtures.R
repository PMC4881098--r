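# Shared fixtures and independent brute-force oracles.

# square village at grid position (i, j), cells of `size` meters
squarePoly <- function(i, j, size = 1000) {
  x0 <- j * size; y0 <- i * size
  cbind(c(x0, x0 + size, x0 + size, x0), c(y0, y0, y0 + size, y0 + size))
}

# nx x ny lattice of square villages, ids in row-major order
latticeVillages <- function(nx, ny, size = 1000) {
  ids <- character(0); polys <- list()
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ids <- c(ids, sprintf("g%d_%d", i, j))
    polys[[length(polys) + 1L]] <- squarePoly(i - 1, j - 1, size)
  }
  villageSet(ids, polys)
}

# SpatialWeights from an explicit binary matrix
makeWeights <- function(w, ids = NULL, rule = "queen", includeSelf = FALSE) {
  n <- nrow(w)
  if (is.null(ids)) ids <- sprintf("v%02d", seq_len(n))
  new("SpatialWeights", ids = ids, w = w, rule = rule,
      includeSelf = includeSelf)
}

# path graph 1-2-...-n
pathWeights <- function(n) {
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
  makeWeights(w)
}

# random symmetric binary weights with at least one link
randomWeights <- function(n, p = 0.4) {
  repeat {
    w <- matrix(0, n, n)
    up <- upper.tri(w)
    w[up] <- rbinom(sum(up), 1, p)
    w <- w + t(w)
    if (sum(w) > 0) return(makeWeights(w))
  }
}

# brute-force Moran's I: literal double sum
bruteMoran <- function(x, w) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
  n * num / (sum(w) * sum((x - xb)^2))
}

# brute-force Gi*: literal per-village evaluation with self-inclusive weights
bruteGiStar <- function(x, w, includeSelf = TRUE) {
  n <- length(x)
  diag(w) <- as.numeric(includeSelf)
  xb <- sum(x) / n
  s <- sqrt(sum(x^2) / n - xb^2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    sw <- 0; sw2 <- 0; sx <- 0
    for (j in seq_len(n)) {
      sw <- sw + w[i, j]; sw2 <- sw2 + w[i, j]^2
      sx <- sx + w[i, j] * x[j]
    }
    z[i] <- (sx - xb * sw) / (s * sqrt((n * sw2 - sw^2) / (n - 1)))
  }
  z
}

# brute-force focal range: explicit window scan
bruteFocalRange <- function(m, window = 3L) {
  half <- window %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- max(1, i - half):min(nr, i + half)
    cj <- max(1, j - half):min(nc, j + half)
    vals <- m[ri, cj]
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[i, j] <- max(vals) - min(vals)
  }
  out
}

# small synthetic config for fast end-to-end tests
smallConfig <- function(seed = 1L, ...) {
  args <- list(gridRows = 40L, gridCols = 40L, nVillages = 30L,
               basinRadius = 10, nPeriods = 2L, seed = seed)
  do.call(syntheticConfig, utils::modifyList(args, list(...)))
}
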