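# Geographically weighted regression: local WLS with distance-decay kernels,
# hat-matrix diagnostics, AICc bandwidth selection and model comparison.

.gwrKernelWeights <- function(d, bandwidth, kernel, adaptive) {
  if (!is.finite(bandwidth)) return(rep(1, length(d)))
  if (adaptive) {
    k <- max(2L, min(length(d), as.integer(round(bandwidth))))
    h <- sort(d, partial = k)[k]
    if (h <= 0) h <- .Machine$double.eps
  } else h <- bandwidth
  if (kernel == "bisquare") {
    w <- (1 - (d / h)^2)^2
    w[d >= h] <- 0
    w
  } else {
    exp(-0.5 * (d / h)^2)
  }
}

# core local-WLS sweep. X includes the intercept column. dmat is the n x n
# distance matrix. full = TRUE additionally accumulates the hat-matrix rows
# (v2, local R2); the bandwidth search runs with full = FALSE.
.gwrCore <- function(y, X, dmat, bandwidth, kernel, adaptive, full = TRUE) {
  n <- length(y)
  p <- ncol(X)
  beta <- matrix(NA_real_, n, p)
  fitted <- numeric(n)
  hat <- numeric(n)
  v2 <- 0
  localR2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- .gwrKernelWeights(dmat[i, ], bandwidth, kernel, adaptive)
    Xw <- X * w
    XtWX <- crossprod(X, Xw)
    A <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(A))
      .numError(paste0("singular local design at location ", i,
                       "; increase the bandwidth"))
    bi <- A %*% crossprod(Xw, y)
    beta[i, ] <- bi
    fitted[i] <- sum(X[i, ] * bi)
    # i-th row of the hat matrix: x_i' (X'WX)^-1 X'W
    ri <- as.numeric(X[i, ] %*% A %*% t(Xw))
    hat[i] <- ri[i]
    if (full) {
      v2 <- v2 + sum(ri^2)
      ybar <- sum(w * y) / sum(w)
      tssw <- sum(w * (y - ybar)^2)
      rssw <- sum(w * (y - as.numeric(X %*% bi))^2)
      localR2[i] <- if (tssw > 0) 1 - rssw / tssw else NA_real_
    }
  }
  res <- y - fitted
  list(beta = beta, fitted = fitted, residuals = res, hat = hat,
       RSS = sum(res^2), v1 = sum(hat), v2 = v2, localR2 = localR2)
}

.gwrAICc <- function(RSS, n, v1) {
  den <- n - 2 - v1
  if (den <= 0) return(Inf)
  n * log(RSS / n) + n * log(2 * pi) + n * (n + v1) / den
}

.standardizeX <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) .dataError("constant covariate cannot be standardized")
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

.asCovariateMatrix <- function(X, n) {
  if (is.null(X)) return(matrix(numeric(0), n, 0))
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X))) .dataError("covariates contain non-finite values")
  X
}

#' Fit a geographically weighted regression
#'
#' Local weighted least squares at every observation location, with kernel
#' weights decaying over geographic distance: adaptive bisquare (bandwidth =
#' number of nearest neighbors, the default, robust to uneven village
#' density) or fixed Gaussian (bandwidth = distance in map units).
#' \code{bandwidth = Inf} gives uniform weights, reducing every local fit to
#' the global OLS fit. Covariates are standardized internally before fitting
#' (stabilizing the bandwidth search); coefficients are reported back on the
#' raw scale, with the standardized-scale coefficients retained alongside.
#'
#' Global diagnostics use the hat matrix S: effective parameters
#' \code{v1 = tr(S)} and \code{v2 = tr(S'S)}, residual variance
#' \code{RSS / (n - 2 v1 + v2)}, standardized residuals
#' \code{e_i / (sigma sqrt(1 - s_ii))}, \code{AICc = n log(RSS/n) +
#' n log(2 pi) + n (n + v1) / (n - 2 - v1)}, and adjusted R2 computed on the
#' effective degrees of freedom.
#'
#' @param y response vector (e.g. smoothed rate per 1e5).
#' @param X covariate matrix or data.frame (no intercept column; NULL for an
#'   intercept-only model).
#' @param coords n x 2 matrix of projected coordinates.
#' @param bandwidth kernel bandwidth: neighbor count (adaptive) or distance
#'   (fixed); \code{Inf} for the global-OLS limit.
#' @param kernel "bisquare" (default) or "gaussian".
#' @param adaptive nearest-neighbor (TRUE) vs fixed-distance bandwidth;
#'   defaults to TRUE for bisquare, FALSE for gaussian.
#' @param standardize standardize covariates internally (default TRUE).
#' @return a [GWRResult-class].
#' @export
fitGWR <- function(y, X, coords, bandwidth, kernel = c("bisquare", "gaussian"),
                   adaptive = NULL, standardize = TRUE) {
  kernel <- match.arg(kernel)
  if (is.null(adaptive)) adaptive <- kernel == "bisquare"
  coords <- as.matrix(coords)
  n <- length(y)
  if (nrow(coords) != n) .dataError("coords do not match the response length")
  if (length(bandwidth) != 1L || is.na(bandwidth) || bandwidth <= 0)
    .configError("bandwidth must be a single positive value (Inf allowed)")
  Xc <- .asCovariateMatrix(X, n)
  xn <- colnames(Xc)
  std <- NULL
  if (standardize && ncol(Xc) > 0) {
    std <- .standardizeX(Xc)
    Xfit <- std$X
  } else Xfit <- Xc
  Xd <- cbind("(Intercept)" = 1, Xfit)
  dmat <- as.matrix(stats::dist(coords))
  fit <- .gwrCore(y, Xd, dmat, bandwidth, kernel, adaptive, full = TRUE)

  betaStd <- fit$beta
  colnames(betaStd) <- c("(Intercept)", xn)
  beta <- betaStd
  if (!is.null(std)) {
    for (j in seq_along(xn)) beta[, j + 1L] <- betaStd[, j + 1L] / std$scale[j]
    beta[, 1L] <- betaStd[, 1L] -
      if (length(xn)) as.numeric(betaStd[, -1L, drop = FALSE] %*%
                                 (std$center / std$scale)) else 0
  }

  tss <- sum((y - mean(y))^2)
  R2 <- if (tss > 0) 1 - fit$RSS / tss else NA_real_
  edf <- n - 2 * fit$v1 + fit$v2
  adjR2 <- if (tss > 0 && edf > 1) 1 - (1 - R2) * (n - 1) / (edf - 1)
           else NA_real_
  sigma2 <- fit$RSS / max(edf, 1e-8)
  lev <- pmin(fit$hat, 1 - 1e-10)
  stdres <- fit$residuals / sqrt(sigma2 * (1 - lev))

  new("GWRResult",
      localCoef = beta, localCoefStd = betaStd, fitted = fit$fitted,
      residuals = fit$residuals, stdResiduals = stdres,
      localR2 = fit$localR2, hatDiag = fit$hat, coords = coords,
      kernel = kernel, adaptive = adaptive, bandwidth = bandwidth,
      v1 = fit$v1, v2 = fit$v2, RSS = fit$RSS, R2 = R2, adjR2 = adjR2,
      AICc = .gwrAICc(fit$RSS, n, fit$v1),
      xNames = c("(Intercept)", xn))
}

#' Select a GWR bandwidth by AICc
#'
#' Golden-section search for the bandwidth minimizing the AICc of the fit.
#' Adaptive bandwidths are searched over neighbor counts (evaluated at
#' integers); fixed bandwidths over distances. Both bounds are themselves
#' evaluated, so data with no spatial coefficient variation select the upper
#' bound (the global-regression limit). The search is deterministic.
#'
#' @param y,X,coords,kernel,adaptive,standardize as in [fitGWR()].
#' @param bounds length-2 search interval; defaults to neighbor counts
#'   \code{c(max(10, 5 p), n)} (adaptive) or \code{c(max
#'   nearest-neighbor distance, study diameter)} (fixed).
#' @param tol convergence tolerance of the golden-section search (1 neighbor
#'   for adaptive, 0.1% of the interval for fixed).
#' @return the selected bandwidth (neighbor count or distance).
#' @export
selectBandwidth <- function(y, X, coords, kernel = c("bisquare", "gaussian"),
                            adaptive = NULL, bounds = NULL,
                            standardize = TRUE, tol = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(adaptive)) adaptive <- kernel == "bisquare"
  coords <- as.matrix(coords)
  n <- length(y)
  if (n < 20L) .dataError("bandwidth selection needs at least 20 observations")
  Xc <- .asCovariateMatrix(X, n)
  if (standardize && ncol(Xc) > 0) Xc <- .standardizeX(Xc)$X
  Xd <- cbind(1, Xc)
  dmat <- as.matrix(stats::dist(coords))
  if (any(dmat[upper.tri(dmat)] == 0))
    .dataError("bandwidth selection requires distinct coordinates")

  p <- ncol(Xd)
  if (is.null(bounds)) {
    bounds <- if (adaptive) c(max(10, 5 * p), n)
              else {
                dNN <- apply(dmat + diag(Inf, n), 1, min)
                c(max(dNN), max(dmat))
              }
  }
  lo <- bounds[1]; hi <- bounds[2]
  if (!(hi > lo)) .configError("bandwidth bounds must satisfy lower < upper")
  if (is.null(tol)) tol <- if (adaptive) 1 else 1e-3 * (hi - lo)

  cache <- new.env(parent = emptyenv())
  obj <- function(b) {
    bEff <- if (adaptive) round(b) else b
    key <- format(bEff, digits = 12)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch({
      fit <- .gwrCore(y, Xd, dmat, bEff, kernel, adaptive, full = FALSE)
      .gwrAICc(fit$RSS, n, fit$v1)
    }, error = function(e) Inf)
    cache[[key]] <- val
    val
  }

  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- obj(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- obj(x2)
    }
  }
  cands <- c(lo, a, (a + b) / 2, b, hi)
  if (adaptive) cands <- unique(round(cands))
  vals <- vapply(cands, obj, numeric(1))
  if (all(!is.finite(vals)))
    .numError("no finite AICc in the search interval; widen the bounds")
  cands[which.min(vals)]
}

#' Coverage of standardized residuals
#'
#' Fraction of locations whose standardized residual lies inside the closed
#' interval \code{bounds} (default [-2, 2], the conventional band for an
#' adequate local fit).
#'
#' @param gwr a [GWRResult-class].
#' @param bounds closed interval, default \code{c(-2, 2)}.
#' @return proportion in [0, 1].
#' @export
stdresidCoverage <- function(gwr, bounds = c(-2, 2)) {
  r <- gwr@stdResiduals
  mean(r >= bounds[1] & r <= bounds[2])
}

#' Compare GWR model variants by AICc
#'
#' Fits one GWR per covariate subset (each with its own AICc-selected
#' bandwidth) on identical observations and ranks the variants by AICc
#' ascending; ties keep the listed order.
#'
#' @param y response vector.
#' @param covariates data.frame of candidate covariates.
#' @param coords n x 2 coordinate matrix.
#' @param variants named list of character vectors of covariate names;
#'   default the single-factor and combined terrain models.
#' @param kernel,adaptive,bounds passed to [selectBandwidth()]/[fitGWR()].
#' @return data.frame ranked by AICc: variant, covariates, bandwidth, AICc,
#'   R2, adjR2, plus the list of fitted [GWRResult-class] objects as the
#'   "fits" attribute.
#' @export
compareGWRModels <- function(y, covariates, coords,
                             variants = list(RDLS = "RDLS", VDC = "VDC",
                                             both = c("RDLS", "VDC")),
                             kernel = c("bisquare", "gaussian"),
                             adaptive = NULL, bounds = NULL) {
  kernel <- match.arg(kernel)
  covariates <- as.data.frame(covariates)
  rows <- vector("list", length(variants))
  fits <- vector("list", length(variants))
  for (k in seq_along(variants)) {
    vars <- variants[[k]]
    if (!all(vars %in% names(covariates)))
      .configError("variant '%s' uses covariates absent from the data: %s",
                   names(variants)[k],
                   paste(setdiff(vars, names(covariates)), collapse = ", "))
    Xk <- as.matrix(covariates[, vars, drop = FALSE])
    bw <- selectBandwidth(y, Xk, coords, kernel = kernel, adaptive = adaptive,
                          bounds = bounds)
    fit <- fitGWR(y, Xk, coords, bandwidth = bw, kernel = kernel,
                  adaptive = adaptive)
    rows[[k]] <- data.frame(
      variant = names(variants)[k],
      covariates = paste(vars, collapse = "+"),
      bandwidth = bw, AICc = fit@AICc, R2 = fit@R2, adjR2 = fit@adjR2,
      stringsAsFactors = FALSE)
    fits[[k]] <- fit
  }
  out <- do.call(rbind, rows)
  names(fits) <- names(variants)
  ord <- order(out$AICc)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
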