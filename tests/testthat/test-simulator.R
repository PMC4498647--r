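test_that("wormlike chains have exact segment lengths and stiff-limit geometry", {
  set.seed(51)
  v <- simulateWormlikeChain(5000, 2000, 1)
  d <- sqrt(rowSums((v[-1, ] - v[-nrow(v), ])^2))
  expect_equal(d, rep(1, 2000), tolerance = 1e-9)
  expect_equal(nrow(v), 2001L)
  # stiff limit: end-to-end distance equals the contour length
  vs <- simulateWormlikeChain(1e12, 1000, 1)
  ee <- sqrt(sum((vs[nrow(vs), ] - vs[1, ])^2))
  expect_equal(ee, 1000, tolerance = 1e-3)
  expect_error(simulateWormlikeChain(-1, 100), "xi")
})

test_that("tangent correlations decay as exp(-s/(2 xi))", {
  set.seed(52)
  xi <- 5000
  nSeg <- 5000
  svals <- c(100, 300, 1000)
  acc <- matrix(0, length(svals), 0)
  cors <- sapply(seq_len(40), function(i) {
    v <- simulateWormlikeChain(xi, nSeg, 1)
    tang <- atan2(diff(v[, 2]), diff(v[, 1]))
    sapply(svals, function(s) mean(cos(tang[(1 + s):nSeg] -
                                         tang[1:(nSeg - s)])))
  })
  est <- rowMeans(cors)
  expect_equal(est, exp(-svals / (2 * xi)), tolerance = 0.02)
})

test_that("parallel companions sit at the fixed perpendicular distance", {
  set.seed(53)
  cfg <- simulationConfig(nFilaments = 3L, nSegments = 2000L, xi = 5000,
                          mode = "parallel", d = 50)
  f1 <- simulateFilaments(cfg)
  f2 <- deriveChannel2(f1, cfg)
  # distance from each channel-2 vertex to the nearest channel-1 vertex
  for (i in seq_along(f1@vertices)) {
    v1 <- f1@vertices[[i]]; v2 <- f2@vertices[[i]]
    idx <- seq(50, nrow(v2) - 50, by = 97)
    dmin <- vapply(idx, function(j) {
      sqrt(min((v1[, 1] - v2[j, 1])^2 + (v1[, 2] - v2[j, 2])^2))
    }, numeric(1))
    expect_lt(max(abs(dmin - 50)), 1)
  }
})

test_that("twisted companions oscillate with the configured period and amplitude", {
  set.seed(54)
  cfg <- simulationConfig(nFilaments = 1L, nSegments = 4000L, xi = 1e9,
                          mode = "twisted", dmax = 50, period = 300)
  f1 <- simulateFilaments(cfg)
  f2 <- deriveChannel2(f1, cfg)
  off <- sqrt(rowSums((f2@vertices[[1]] - f1@vertices[[1]])^2))
  expect_equal(max(off), 50, tolerance = 1e-3)
  # zero crossings of the signed offset are half a period apart
  v1 <- f1@vertices[[1]]
  nrm <- coorient:::.polylineNormals(v1)
  signed <- rowSums((f2@vertices[[1]] - v1) * nrm)
  zc <- which(diff(sign(signed)) != 0)
  expect_equal(median(diff(zc)), 150, tolerance = 2)
  expect_error(deriveChannel2(f1, simulationConfig(mode = "independent",
                                                   xi2 = -1)), "xi2")
})

test_that("filament density rendering conserves mass and uses the right kernel width", {
  set.seed(55)
  cfg <- simulationConfig(nFilaments = 1L, nSegments = 1000L, xi = 1e9)
  # place a straight interior filament manually
  v <- cbind(seq(500, 1499, length.out = 1001), rep(1000, 1001))
  fs <- new("FilamentSet", vertices = list(v), segLen = 1, xi = 1e9)
  den <- renderFilamentDensity(fs, bin = 5, blurFwhm = 5,
                               extent = c(0, 2000, 0, 2000))
  expect_equal(sum(values(den)), 1001, tolerance = 1e-3)
  # without blur, counts lie on a one-pixel-wide line
  den0 <- renderFilamentDensity(fs, bin = 5, blurFwhm = 0,
                                extent = c(0, 2000, 0, 2000))
  rows <- which(rowSums(values(den0)) > 0)
  expect_equal(length(rows), 1L)
  expect_equal(sum(values(den0)), 1001)
  # FWHM to sigma conversion
  expect_equal(coorient:::.fwhmToSigma(5), 5 / 2.3548, tolerance = 1e-4)
})

test_that("fluorophore sampling is Poisson in count and proportional in space", {
  set.seed(56)
  den <- new("PixelImage", values = matrix(1, 50, 50), binSize = 10,
             origin = c(0, 0), nDropped = 0L)
  expect_equal(nrow(sampleFluorophores(den, 0)), 0L)
  pts <- sampleFluorophores(den, 4000, jitterFwhm = 0)
  expect_lt(abs(nrow(pts) - 4000), 4 * sqrt(4000))
  # uniform density: quadrant counts consistent with uniformity
  qx <- pts[, 1] > 250; qy <- pts[, 2] > 250
  tab <- table(qx, qy)
  expect_gt(chisq.test(tab)$p.value, 1e-4)
  zero <- new("PixelImage", values = matrix(0, 5, 5), binSize = 10,
              origin = c(0, 0), nDropped = 0L)
  expect_error(sampleFluorophores(zero, 10), "all-zero")
})

test_that("blink counts follow min(Poisson, Geometric) with the stated means", {
  set.seed(57)
  # independent Monte-Carlo oracle for E[min(Pois(25), Geo(11))]
  nmc <- 2e5
  oracle <- mean(pmin(rpois(nmc, 25), rgeom(nmc, 1 / 11) + 1))
  cfg <- simulationConfig(nFluorophores = 1e4)
  pts <- cbind(runif(10000, 0, 4000), runif(10000, 0, 4000))
  locs <- simulateLocalizations(pts, cfg)
  counts <- table(factor(localizations(locs)$fluorophore,
                         levels = seq_len(10000)))
  expect_equal(mean(counts), oracle, tolerance = 0.02)
  # geometric convention: photon counts have mean 2000 on support {1, 2, ...}
  expect_gte(min(localizations(locs)$photons), 1)
  expect_equal(mean(localizations(locs)$photons), 2000, tolerance = 0.05)
})

test_that("the localization precision model behaves as published", {
  set.seed(58)
  cfg <- simulationConfig()
  pts <- cbind(runif(5000, 0, 4000), runif(5000, 0, 4000))
  locs <- simulateLocalizations(pts, cfg)
  r <- localizations(locs)
  # PSF width draws: recover mean 1.38 px within standard error
  nL <- nrow(r)
  expect_equal(mean(r$sigma > 0), 1)
  # more photons give stochastically better precision
  expect_lt(cor(r$photons, r$sigma, method = "spearman"), -0.8)
  # direct check of the precision formula at nominal parameters
  sigmaNominal <- coorient:::.localizationPrecision(2000, 1, 138, 100)
  sa2 <- 138^2 + 100^2 / 12
  expect_equal(sigmaNominal,
               sqrt(sa2 / 2000 * (16 / 9 + 8 * pi * sa2 * 1 / (2000 * 1e4))),
               tolerance = 1e-12)
  # PSF width population mean (re-derived from the draws)
  sa <- rnorm(2e4, cfg@psfWidthPx, cfg@psfWidthRelSd * cfg@psfWidthPx)
  expect_equal(mean(sa), 1.38, tolerance = 3 * 0.0276 / sqrt(2e4))
  # frames are consecutive within a blink train
  byf <- split(r$frame, r$fluorophore)
  long <- byf[lengths(byf) > 2][1:20]
  for (fr in long) expect_equal(sort(fr), seq(min(fr), length.out = length(fr)))
})

test_that("Gaussian blob rendering is unit-mass per localization", {
  locs <- LocalizationSet(200, 200, 20, 1000, 1L)
  img <- renderGaussianBlobs(locs, 10, extent = c(0, 400, 0, 400))
  expect_equal(sum(values(img)), 1, tolerance = 1e-3)
  pk <- which(values(img) == max(values(img)), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(21, 21))
  set.seed(59)
  many <- uniformLocs(200, 1000, sigma = 15)
  imgM <- renderGaussianBlobs(many, 10, extent = c(-100, 1100, -100, 1100))
  expect_equal(sum(values(imgM)), 200, tolerance = 0.01)
  noSigma <- LocalizationSet(1, 1, 1, 1, 1L)
  noSigma@records$sigma <- NA_real_
  expect_error(renderGaussianBlobs(noSigma, 10, c(0, 10, 0, 10)), "precision")
})

test_that("one master seed reproduces a dataset bit for bit", {
  s1 <- simulateDataset("twisted", seed = 99, nFilaments = 12L,
                        nFluorophores = 300, fov = 1000)
  s2 <- simulateDataset("twisted", seed = 99, nFilaments = 12L,
                        nFluorophores = 300, fov = 1000)
  expect_identical(localizations(s1$locs1), localizations(s2$locs1))
  expect_identical(localizations(s1$locs2), localizations(s2$locs2))
  expect_identical(s1$filaments2@vertices, s2$filaments2@vertices)
})
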