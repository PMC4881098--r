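#' Local Getis-Ord Gi* statistics
#'
#' For each village i, with binary weights including the village itself (the
#' defining convention of the starred statistic):
#' \deqn{G_i^* = \frac{\sum_j \omega_{ij} x_j - \bar X \sum_j \omega_{ij}}
#'   {S \sqrt{[n \sum_j \omega_{ij}^2 - (\sum_j \omega_{ij})^2] / (n - 1)}}}
#' with \eqn{\bar X = \sum_j x_j / n} and
#' \eqn{S = \sqrt{\sum_j x_j^2 / n - \bar X^2}} taken over all n villages.
#' The statistic is already a z-score; two-sided normal p-values are
#' attached. Setting \code{includeSelf = FALSE} yields the plain Gi
#' statistic (the focal village is dropped from its own neighborhood).
#'
#' @param x attribute values aligned with \code{W} ids; non-constant.
#' @param W a [SpatialWeights-class]; the diagonal is forced to match
#'   \code{includeSelf}.
#' @param includeSelf include each village in its own neighborhood
#'   (default TRUE, the Gi* convention).
#' @return data.frame: village_id, x, gi_z, p_value, and hotspot
#'   \code{class} from [classifyHotspots()].
#' @export
giStar <- function(x, W, includeSelf = TRUE) {
  n <- length(x)
  if (n != length(W@ids))
    .dataError("attribute length %d does not match %d villages", n,
               length(W@ids))
  if (n < 3L) .dataError("Gi* needs at least 3 villages")
  if (any(!is.finite(x))) .dataError("attribute contains non-finite values")
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  if (s == 0) .numError("Gi* is undefined for a constant attribute")
  w <- W@w
  diag(w) <- as.numeric(includeSelf)
  wi <- rowSums(w)               # binary weights: sum w == sum w^2
  num <- as.numeric(w %*% x) - xbar * wi
  den <- s * sqrt((n * wi - wi^2) / (n - 1))
  z <- ifelse(den > 0, num / den, 0)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(village_id = W@ids, x = x, gi_z = z, p_value = p,
             class = classifyHotspots(z), stringsAsFactors = FALSE)
}

#' Classify Gi* z-scores into hotspot classes
#'
#' Two-sided normal thresholds: |z| >= 2.576 gives the 99% class,
#' otherwise |z| >= 1.960 the 95% class, otherwise not significant; the sign
#' separates hot from cold. A z-score near zero implies no local clustering.
#'
#' @param z Gi* z-scores.
#' @return ordered factor with levels cold99 < cold95 < ns < hot95 < hot99.
#' @examples
#' classifyHotspots(c(-3, -2, 0, 2, 3))
#' @export
classifyHotspots <- function(z) {
  lv <- c("cold99", "cold95", "ns", "hot95", "hot99")
  cls <- ifelse(z >= 2.576, "hot99",
         ifelse(z >= 1.960, "hot95",
         ifelse(z <= -2.576, "cold99",
         ifelse(z <= -1.960, "cold95", "ns"))))
  factor(cls, levels = lv, ordered = TRUE)
}

#' Persistent hotspots across periods
#'
#' Villages classified hot at the 95% level or stronger in every period —
#' the stable high-risk core of a multi-period study.
#'
#' @param tables list of Gi* tables (from [giStar()]), one per period, over
#'   an identical village set.
#' @return character vector of persistent hotspot village ids.
#' @export
persistentHotspots <- function(tables) {
  if (length(tables) < 2L)
    .configError("persistent hotspots need at least 2 periods")
  ids <- sort(tables[[1]]$village_id)
  for (k in seq_along(tables)) {
    idk <- sort(tables[[k]]$village_id)
    if (!identical(ids, idk)) {
      diff <- c(setdiff(ids, idk), setdiff(idk, ids))
      .dataError("village sets differ between periods: %s",
                 paste(diff, collapse = ", "))
    }
  }
  hotSets <- lapply(tables, function(t)
    t$village_id[t$class %in% c("hot95", "hot99")])
  Reduce(intersect, hotSets)
}
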