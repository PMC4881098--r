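test_that("the generator is bit-reproducible from config and seed", {
  cfg <- smallConfig(seed = 4L)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(gridValues(s1@dem), gridValues(s2@dem))
  expect_identical(polygons(s1@villages), polygons(s2@villages))
  expect_identical(gridValues(s1@residential), gridValues(s2@residential))
  expect_identical(s1@mortality, s2@mortality)
  # and different seeds change the outcome
  s3 <- simulateStudy(smallConfig(seed = 5L))
  expect_false(identical(s1@mortality$deaths, s3@mortality$deaths))
})

test_that("a degenerate config yields a constant raster", {
  cfg <- smallConfig(roughnessSd = 0, basinDepth = 0, trendRange = 0)
  dem <- generateDEM(cfg)
  expect_true(all(gridValues(dem) == cfg@plateau))
})

test_that("the basin floor sits below the surrounding ring", {
  cfg <- syntheticConfig(seed = 1L)
  dem <- generateDEM(cfg)
  v <- gridValues(dem)
  rc <- expand.grid(r = seq_len(nrow(v)), c = seq_len(ncol(v)))
  d <- sqrt((rc$r - cfg@basinCenter[1])^2 + (rc$c - cfg@basinCenter[2])^2)
  basin <- mean(v[d <= cfg@basinRadius])
  ring <- mean(v[d > cfg@basinRadius & d <= cfg@basinRadius + 20])
  expect_lt(basin, ring)
  expect_gt(ring - basin, 50)   # a pronounced pocket, not noise
})

test_that("config invariants are enforced", {
  expect_error(syntheticConfig(gridRows = 0), "positive")
  expect_error(syntheticConfig(popRange = c(100, 40000)), "30,000")
  expect_error(syntheticConfig(basinRadius = 80, gridRows = 100,
                               gridCols = 100), "extent")
  cfg <- smallConfig()
  expect_error(generateVillages(generateDEM(cfg),
                                smallConfig(nVillages = 2000L)),
               "cell count")
})

test_that("corner seeds tessellate a square grid into quadrants", {
  cfg <- syntheticConfig(gridRows = 10L, gridCols = 10L, nVillages = 4L,
                         basinRadius = 2)
  dem <- generateDEM(cfg)
  pts <- cbind(c(250, 750, 250, 750), c(250, 250, 750, 750))
  vs <- generateVillages(dem, cfg, seedPoints = pts)
  expect_equal(unname(villageAreas(vs)), rep(0.25, 4))
  ctr <- centroids(vs)
  expect_equal(ctr$x, c(250, 750, 250, 750))
  expect_equal(ctr$y, c(250, 250, 750, 750))
})

test_that("Voronoi polygon areas tile the full grid", {
  for (s in c(2L, 6L)) {
    cfg <- smallConfig(seed = s)
    dem <- generateDEM(cfg)
    vs <- generateVillages(dem, cfg)
    gridArea <- cfg@gridRows * cfg@gridCols * (cfg@cellSize / 1000)^2
    expect_equal(sum(villageAreas(vs)), gridArea,
                 tolerance = 1e-3)
    expect_true(all(villageAreas(vs) > 0))
    # determinism of the tessellation
    vs2 <- generateVillages(dem, cfg)
    expect_identical(polygons(vs), polygons(vs2))
  }
})

test_that("residential placement is enriched in flat cells", {
  cfg <- syntheticConfig(seed = 8L)
  dem <- generateDEM(cfg)
  vs <- generateVillages(dem, cfg)
  flat <- extractRFA(focalRange(dem), 30)
  res <- generateResidentialMask(dem, vs, cfg, flat = flat)
  fv <- gridValues(flat); rv <- gridValues(res)
  flatShareRes <- mean(fv[rv == 1])
  flatShareAll <- mean(fv)
  expect_gt(flatShareRes, flatShareAll)
  # every village has at least one residential cell
  mem <- villageMembership(dem, vs)
  tab <- table(mem[rv == 1])
  expect_equal(length(tab), length(vs))
})

test_that("unit bias factor places residences independently of flatness", {
  # pool counts over seeds; chi-square association test should not fire
  tot <- matrix(0, 2, 2)
  for (s in 1:6) {
    cfg <- smallConfig(seed = 100L + s, flatBias = 1)
    dem <- generateDEM(cfg)
    vs <- generateVillages(dem, cfg)
    flat <- extractRFA(focalRange(dem), 30)
    res <- generateResidentialMask(dem, vs, cfg, flat = flat)
    fv <- as.vector(gridValues(flat)); rv <- as.vector(gridValues(res))
    tot <- tot + table(factor(fv, 0:1), factor(rv, 0:1))
  }
  expect_gt(suppressWarnings(chisq.test(tot)$p.value), 0.01)
})

test_that("an all-flat DEM neutralizes the placement bias", {
  cfg <- smallConfig(roughnessSd = 0, basinDepth = 0, trendRange = 0)
  dem <- generateDEM(cfg)
  vs <- generateVillages(dem, cfg)
  res4 <- generateResidentialMask(dem, vs, cfg)
  resCfg1 <- smallConfig(roughnessSd = 0, basinDepth = 0, trendRange = 0,
                         flatBias = 1)
  res1 <- generateResidentialMask(dem, vs, resCfg1)
  # same seed, all cells flat: bias has no effect at all
  expect_identical(gridValues(res4), gridValues(res1))
})

test_that("the null mortality model shares one expected rate", {
  cfg <- smallConfig(betaVdc = 0, betaRdls = 0, noiseSd = 0)
  study <- simulateStudy(cfg)
  expect_true(all(study@truth$expected_rate == cfg@baselineRate))
})

test_that("a positive VDC slope yields positive rate-VDC correlation", {
  cfg <- syntheticConfig(betaVdc = 2, betaRdls = 0, noiseSd = 0,
                         popRange = c(20000, 20000), seed = 1L)
  study <- simulateStudy(cfg)
  topo <- study@topography
  hits <- 0L
  for (s in 1:100) {
    mort <- generateMortality(topo, cfg, seed = 5000L + s)
    tb <- crudeRates(mort$mortality[mort$mortality$period == "P1", ])
    r <- cor(tb$crude_rate, topo$VDC[match(tb$village_id, topo$village_id)],
             use = "complete.obs")
    if (r > 0) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("zero-population villages are excluded with zero deaths", {
  cfg <- smallConfig(popRange = c(0, 0))
  study <- simulateStudy(cfg)
  expect_true(all(study@mortality$excluded))
  expect_true(all(study@mortality$deaths == 0))
})

test_that("basin villages are flatter-floored than ring villages", {
  cfg <- syntheticConfig(seed = 2L)
  study <- simulateStudy(cfg)
  topo <- study@topography
  ctr <- c(cfg@basinCenter[2] * cfg@cellSize,
           (cfg@gridRows - cfg@basinCenter[1]) * cfg@cellSize)
  d <- sqrt((topo$x - ctr[1])^2 + (topo$y - ctr[2])^2) / cfg@cellSize
  basin <- d <= 0.8 * cfg@basinRadius
  ring <- d > cfg@basinRadius & d <= cfg@basinRadius + 20
  expect_gt(sum(basin), 3); expect_gt(sum(ring), 3)
  expect_lt(mean(topo$RDLS[basin]), mean(topo$RDLS[ring]))
  expect_gt(mean(topo$VDC[basin], na.rm = TRUE),
            mean(topo$VDC[ring], na.rm = TRUE))
})
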