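test_that("Pearson correlation handles exact linearity and a frozen fixture", {
  a <- c(2.1, 3.4, 1.2, 5.6, 4.4, 3.3, 2.2, 6.1, 0.5, 4.9)
  expect_equal(pearsonCorrelation(a, 2 * a + 1)$r, 1)
  expect_equal(pearsonCorrelation(a, -a)$r, -1)
  b <- c(1.0, 2.9, 0.7, 4.1, 4.8, 2.0, 1.1, 5.5, 0.2, 3.6)
  out <- pearsonCorrelation(a, b, "a~b")
  # frozen value from the textbook product-moment formula evaluated
  # independently
  expect_equal(out$r, 0.9511372314391593, tolerance = 1e-12)
  expect_equal(out$n, 10L)
  expect_lt(out$p_value, 0.01)
  # invariance under affine rescaling of either variable
  expect_equal(pearsonCorrelation(10 * a - 3, b)$r, out$r, tolerance = 1e-12)
  expect_equal(pearsonCorrelation(a, b / 7 + 2)$r, out$r, tolerance = 1e-12)
  expect_error(pearsonCorrelation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearsonCorrelation(1:2, 2:1), "3 pairs")
})

test_that("GWR at infinite bandwidth equals global least squares", {
  set.seed(41)
  n <- 60
  co <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
  X <- cbind(a = rnorm(n), b = runif(n))
  y <- 1 + 2 * X[, 1] - 0.5 * X[, 2] + rnorm(n, 0, 0.3)
  g <- fitGWR(y, X, co, bandwidth = Inf)
  ols <- unname(coef(lm(y ~ X)))
  for (i in seq_len(n))
    expect_equal(unname(g@localCoef[i, ]), ols, tolerance = 1e-8)
  expect_equal(g@fitted, unname(fitted(lm(y ~ X))), tolerance = 1e-8)
})

test_that("intercept-only GWR gives R2 = 0 and the closed-form AICc", {
  set.seed(43)
  n <- 40
  co <- cbind(runif(n), runif(n))
  y <- rnorm(n)
  g <- fitGWR(y, NULL, co, bandwidth = Inf)
  expect_equal(g@R2, 0, tolerance = 1e-12)
  rss <- sum((y - mean(y))^2)
  expect_equal(g@AICc,
               n * log(rss / n) + n * log(2 * pi) + n * (n + 1) / (n - 3),
               tolerance = 1e-10)
})

test_that("local slopes recover a west-east coefficient gradient", {
  set.seed(47)
  n <- 300
  co <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
  slope <- 1 + 2 * co[, 1] / 1e4          # true slope rises west to east
  x <- rnorm(n)
  y <- 0.5 + slope * x + rnorm(n, 0, 0.05)
  g <- fitGWR(y, cbind(x = x), co, bandwidth = 40)
  expect_gt(cor(g@localCoef[, "x"], slope), 0.9)
})

test_that("bandwidth selection is deterministic and hits the global limit", {
  set.seed(53)
  n <- 80
  co <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
  X <- cbind(x = rnorm(n))
  # no spatial variation: a single global linear model
  yGlobal <- 2 + 3 * X[, 1] + rnorm(n, 0, 0.1)
  b1 <- selectBandwidth(yGlobal, X, co)
  b2 <- selectBandwidth(yGlobal, X, co)
  expect_identical(b1, b2)
  expect_gte(b1, 0.95 * n)   # upper bound = n neighbors
  # strong coefficient gradient: selected bandwidth pulls below the bound
  slope <- 1 + 4 * co[, 1] / 1e4
  yLocal <- slope * X[, 1] + rnorm(n, 0, 0.05)
  bLocal <- selectBandwidth(yLocal, X, co)
  expect_lt(bLocal, 0.8 * n)
})

test_that("standardization changes neither fit nor raw-scale coefficients", {
  set.seed(59)
  n <- 70
  co <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
  X <- cbind(u = rnorm(n, 50, 10), v = runif(n, 0, 1))
  y <- 1 + 0.2 * X[, 1] - 2 * X[, 2] + rnorm(n, 0, 0.2)
  gs <- fitGWR(y, X, co, bandwidth = 30, standardize = TRUE)
  gr <- fitGWR(y, X, co, bandwidth = 30, standardize = FALSE)
  expect_equal(gs@fitted, gr@fitted, tolerance = 1e-8)
  expect_equal(gs@localCoef, gr@localCoef, tolerance = 1e-6)
  expect_equal(gs@AICc, gr@AICc, tolerance = 1e-8)
})

test_that("standardized-residual coverage counts the closed interval", {
  set.seed(61)
  n <- 50
  co <- cbind(runif(n), runif(n))
  x <- rnorm(n)
  g <- fitGWR(2 * x + rnorm(n), cbind(x = x), co, bandwidth = Inf)
  # exactly-zero residual surface -> full coverage, for any bounds
  g@stdResiduals <- rep(0, n)
  expect_equal(stdresidCoverage(g, c(-2, 2)), 1)
  expect_equal(stdresidCoverage(g, c(0, 0)), 1)  # degenerate closed bounds
  g@stdResiduals <- c(rep(0, 10), rep(2, 20), rep(-5, 20))
  expect_equal(stdresidCoverage(g, c(-2, 2)), 0.6)  # boundary inclusive
  expect_equal(stdresidCoverage(g, c(0, 0)), 0.2)
})

test_that("well-specified fits keep ~95% of standardized residuals in [-2,2]", {
  covers <- sapply(1:5, function(s) {
    set.seed(70 + s)
    n <- 300
    co <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
    x <- rnorm(n)
    y <- 1 + (1 + co[, 1] / 1e4) * x + rnorm(n)
    g <- fitGWR(y, cbind(x = x), co, bandwidth = 60)
    stdresidCoverage(g)
  })
  expect_true(all(covers >= 0.90 & covers <= 0.99))
})

test_that("model comparison ranks variants by AICc with sane structure", {
  set.seed(83)
  n <- 120
  co <- cbind(runif(n, 0, 1e4), runif(n, 0, 1e4))
  covs <- data.frame(RDLS = rnorm(n, 2.8, 0.5), VDC = runif(n))
  y <- 2 + 3 * covs$VDC + rnorm(n, 0, 0.3)
  cmp <- compareGWRModels(y, covs, co,
                          variants = list(RDLS = "RDLS", VDC = "VDC",
                                          both = c("RDLS", "VDC"),
                                          VDC2 = "VDC"))
  expect_equal(cmp$AICc, sort(cmp$AICc))
  # duplicate variants give identical rows
  expect_equal(cmp$AICc[cmp$variant == "VDC"], cmp$AICc[cmp$variant == "VDC2"])
  expect_error(compareGWRModels(y, covs, co, variants = list(z = "huh")),
               "absent")
  # nesting at a common bandwidth: the larger model never fits worse
  g1 <- fitGWR(y, as.matrix(covs["VDC"]), co, bandwidth = 50)
  g2 <- fitGWR(y, as.matrix(covs), co, bandwidth = 50)
  expect_gte(g2@R2, g1@R2 - 1e-10)
})

test_that("singular local designs and bad bandwidths raise fit errors", {
  set.seed(89)
  n <- 30
  co <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  X <- cbind(x = rnorm(n), xc = NA_real_)
  X[, 2] <- X[, 1]  # collinear pair
  expect_error(fitGWR(rnorm(n), X, co, bandwidth = 10), "singular|location")
  expect_error(fitGWR(rnorm(n), cbind(x = rnorm(n)), co, bandwidth = -1),
               "bandwidth")
})
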