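#' Global Moran's I
#'
#' Spatial autocorrelation of an attribute over binary contiguity weights:
#' \deqn{I = \frac{N \sum_i \sum_j \omega_{ij} (x_i - \bar x)(x_j - \bar x)}
#'   {(\sum_i \sum_j \omega_{ij}) \sum_i (x_i - \bar x)^2}}
#' Positive values indicate clustering of similar values among contiguous
#' villages, negative values dispersion. The weights are used exactly as
#' given (binary, not row-standardized); any self-weights on the diagonal
#' are removed first.
#'
#' @param x attribute values aligned with \code{W} ids (village-level
#'   smoothed rate, VDC, RDLS, ...). Must be non-constant and free of NA.
#' @param W a [SpatialWeights-class].
#' @return the Moran's I statistic.
#' @export
moransI <- function(x, W) {
  w <- W@w
  diag(w) <- 0
  n <- length(x)
  if (n != length(W@ids))
    .dataError("attribute length %d does not match %d villages", n,
               length(W@ids))
  if (n < 3L) .dataError("Moran's I needs at least 3 villages")
  if (any(!is.finite(x))) .dataError("attribute contains non-finite values")
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) .numError("Moran's I is undefined for a constant attribute")
  s0 <- sum(w)
  if (s0 == 0) .dataError("weights matrix has no links")
  n * as.numeric(crossprod(z, w %*% z)) / (s0 * ss)
}

# permutation distribution of I via the edge list, all permutations at once
.moranPermI <- function(x, w, nPerm) {
  e <- which(w == 1 & upper.tri(w), arr.ind = TRUE)
  s0 <- sum(w)
  n <- length(x)
  Z <- vapply(seq_len(nPerm), function(k) sample(x), numeric(n))
  Z <- Z - rep(colMeans(Z), each = n)
  num <- 2 * colSums(Z[e[, 1], , drop = FALSE] * Z[e[, 2], , drop = FALSE])
  ss <- colSums(Z^2)
  n * num / (s0 * ss)
}

#' Inference for Moran's I
#'
#' Permutation inference (default): the attribute is randomly reassigned to
#' villages \code{nPerm} times; the pseudo p-value follows the +1 convention,
#' \eqn{p_{dir} = (1 + \#\{I^{perm} \ge I^{obs}\}) / (nPerm + 1)} for an
#' observed I above its permutation mean (mirrored below), reported two-sided
#' as \code{min(1, 2 p_dir)}; the z-score standardizes the observed I by the
#' permutation mean and sd. The analytic option uses the classical
#' randomization moments of I (normal approximation).
#'
#' @param x attribute values aligned with \code{W} ids.
#' @param W a [SpatialWeights-class].
#' @param method "permutation" (default) or "analytic".
#' @param nPerm number of permutations (>= 99 recommended; fewer warns).
#' @param seed integer seed for the permutation draw (required for
#'   reproducibility; default 1).
#' @param alternative "two.sided" (default) or "directional" (the mirrored
#'   one-sided pseudo p).
#' @return a [MoranResult-class].
#' @export
moransITest <- function(x, W, method = c("permutation", "analytic"),
                        nPerm = 999L, seed = 1L,
                        alternative = c("two.sided", "directional")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  obs <- moransI(x, W)
  n <- length(x)
  e0 <- -1 / (n - 1)
  w <- W@w
  diag(w) <- 0

  if (method == "permutation") {
    nPerm <- as.integer(nPerm)
    if (nPerm < 99L)
      warning("fewer than 99 permutations gives a coarse p-value")
    set.seed(as.integer(seed))
    sims <- .moranPermI(x, w, nPerm)
    mu <- mean(sims); sdv <- stats::sd(sims)
    z <- if (sdv > 0) (obs - mu) / sdv else NA_real_
    pDir <- if (obs >= mu) (1 + sum(sims >= obs)) / (nPerm + 1)
            else (1 + sum(sims <= obs)) / (nPerm + 1)
    p <- if (alternative == "two.sided") min(1, 2 * pDir) else pDir
    new("MoranResult", I = obs, expectation = e0, zScore = z, pValue = p,
        method = "permutation", nPerm = nPerm, seed = as.integer(seed),
        n = as.integer(n))
  } else {
    # randomization moments (Cliff & Ord)
    s0 <- sum(w)
    s1 <- sum((w + t(w))^2) / 2
    s2 <- sum((rowSums(w) + colSums(w))^2)
    z4 <- x - mean(x)
    b2 <- n * sum(z4^4) / sum(z4^2)^2
    num <- n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
      b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)
    vI <- num / ((n - 1) * (n - 2) * (n - 3) * s0^2) - e0^2
    if (vI <= 0) .numError("non-positive randomization variance of I")
    z <- (obs - e0) / sqrt(vI)
    p <- 2 * stats::pnorm(-abs(z))
    if (alternative == "directional") p <- stats::pnorm(-abs(z))
    p <- max(p, .Machine$double.xmin)
    new("MoranResult", I = obs, expectation = e0, zScore = z, pValue = p,
        method = "analytic", nPerm = 0L, seed = NA_integer_,
        n = as.integer(n))
  }
}
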