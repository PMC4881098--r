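#' Adjust death counts for underreporting
#'
#' Registered deaths are inflated by the regional underreporting fraction:
#' \code{adjusted = deaths / (1 - fraction)}. The result is real-valued; it
#' feeds the rate computations, not a count model.
#'
#' @param deaths non-negative death counts.
#' @param fraction proportion of deaths missed, in [0, 1). May be a vector
#'   (per-region rates) recycled against \code{deaths}.
#' @return adjusted death counts.
#' @examples
#' adjustUnderreporting(90, 0.1)  # 100
#' @export
adjustUnderreporting <- function(deaths, fraction) {
  if (any(fraction < 0) || any(fraction >= 1))
    .configError("underreporting fraction must lie in [0, 1)")
  if (any(deaths < 0)) .dataError("negative death counts")
  deaths / (1 - fraction)
}

#' Crude mortality rates per 100,000
#'
#' Adds \code{crude_rate = 1e5 * deaths / population} to a mortality table.
#' Villages with zero population are flagged \code{excluded} and keep an
#' \code{NA} rate.
#'
#' @param table data.frame with \code{deaths} and \code{population} columns
#'   (extra columns pass through).
#' @return the table with \code{crude_rate} and \code{excluded} columns.
#' @export
crudeRates <- function(table) {
  if (!all(c("deaths", "population") %in% names(table)))
    .dataError("mortality table needs 'deaths' and 'population' columns")
  if (any(table$deaths < 0) || any(table$population < 0))
    .dataError("negative deaths or population")
  table$excluded <- table$population == 0
  table$crude_rate <- ifelse(table$excluded, NA_real_,
                             1e5 * table$deaths / table$population)
  table
}

#' Spatial empirical Bayes rate smoothing
#'
#' Shrinks each village's crude rate toward a locally varying reference mean
#' computed over the village and its contiguity neighbors (the "spatial" EB
#' estimator of disease mapping). For village i with neighborhood
#' N(i) = neighbors plus i itself (k_i units):
#' \deqn{m_i = \sum_{j \in N(i)} d_j / \sum_{j \in N(i)} p_j}
#' \deqn{s_i^2 = \frac{\sum_j p_j (r_j - m_i)^2}{\sum_j p_j} -
#'       \frac{m_i}{\sum_j p_j / k_i}}
#' with the prior variance floored at zero, shrinkage weight
#' \eqn{w_i = s_i^2 / (s_i^2 + m_i / p_i)} and
#' \eqn{\hat r_i = w_i r_i + (1 - w_i) m_i}. All rates are computed as raw
#' proportions internally and reported per 100,000; when the floored prior
#' variance is zero the estimate collapses to the local mean. The smoothed
#' rate always lies between the crude rate and the local mean.
#'
#' @param table mortality table for one period with \code{village_id},
#'   \code{deaths}, \code{population} (after any underreporting adjustment).
#'   Zero-population villages are excluded from smoothing.
#' @param W a [SpatialWeights-class] over (at least) the table's villages;
#'   self-inclusion in \code{W} is ignored — the neighborhood used here is
#'   always neighbors-plus-self.
#' @return the table with \code{crude_rate}, \code{smoothed_rate} (per 1e5)
#'   and \code{excluded} columns.
#' @export
spatialEBSmooth <- function(table, W) {
  table <- crudeRates(table)
  ids <- as.character(table$village_id)
  if (anyDuplicated(ids))
    .dataError("duplicate village_id in one smoothing period")
  pos <- match(ids, W@ids)
  if (any(is.na(pos)))
    .dataError("villages missing from the weights: %s",
               paste(ids[is.na(pos)], collapse = ", "))
  w <- W@w[pos, pos, drop = FALSE]
  diag(w) <- 0

  inc <- which(!table$excluded)
  d <- table$deaths[inc]
  p <- table$population[inc]
  r <- d / p
  wInc <- w[inc, inc, drop = FALSE]
  smoothed <- rep(NA_real_, nrow(table))
  isolates <- character(0)

  for (k in seq_along(inc)) {
    nb <- c(k, which(wInc[k, ] == 1))
    if (length(nb) == 1L) isolates <- c(isolates, ids[inc[k]])
    ki <- length(nb)
    sp <- sum(p[nb])
    m <- sum(d[nb]) / sp
    s2 <- sum(p[nb] * (r[nb] - m)^2) / sp - m / (sp / ki)
    s2 <- max(s2, 0)
    denom <- s2 + m / p[k]
    wk <- if (denom > 0) s2 / denom else 0
    smoothed[inc[k]] <- wk * r[k] + (1 - wk) * m
  }
  if (length(isolates))
    warning("villages with no neighbors smoothed on self only: ",
            paste(isolates, collapse = ", "))
  table$smoothed_rate <- smoothed * 1e5
  table
}

#' Five-level rate categories relative to a reference rate
#'
#' Bands a rate against multiples of the reference rate R0 (for mortality
#' mapping, the national rural age-standardized rate): category 1 below R0,
#' then one category per fold up to category 5 at or above 4 x R0. Intervals
#' are half-open with the lower bound inclusive, so a rate exactly at k x R0
#' falls in category k + 1.
#'
#' @param rate rates per 1e5 (NA passes through).
#' @param R0 reference rate per 1e5, > 0.
#' @return integer categories 1-5.
#' @examples
#' categorizeRates(c(10, 25, 45, 65, 85), R0 = 20)  # 1 2 3 4 5
#' @export
categorizeRates <- function(rate, R0) {
  if (length(R0) != 1L || !is.finite(R0) || R0 <= 0)
    .configError("reference rate R0 must be a single positive number")
  if (any(rate < 0, na.rm = TRUE)) .dataError("negative rates")
  cat <- pmin(floor(rate / R0) + 1L, 5L)
  as.integer(cat)
}
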