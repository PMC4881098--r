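#' Pearson correlation with a two-sided t-test
#'
#' Thin wrapper around \code{stats::cor.test} returning a one-row result in
#' the layout of a correlation table (pair label, r, p, n). Pairs with
#' missing values in either variable are dropped first.
#'
#' @param a,b paired numeric vectors.
#' @param label pair label, e.g. "rate~RDLS".
#' @return data.frame with columns pair, r, p_value, n.
#' @export
pearsonCorrelation <- function(a, b, label = "a~b") {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) .dataError("Pearson correlation needs at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    .numError("Pearson correlation is undefined for a constant input")
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  data.frame(pair = label, r = unname(ct$estimate),
             p_value = ct$p.value, n = n, stringsAsFactors = FALSE)
}
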