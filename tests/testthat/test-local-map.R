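test_that("subregion center grid follows the 3R / R geometry", {
  set.seed(41)
  # image of side 9R gives a 7x7 grid of centers
  R <- 100; a <- 10
  n <- 9 * R / a
  s1 <- stackFromArray(array(runif(n * n * 5, 0.5, 1), c(n, n, 5)))
  s2 <- stackFromArray(array(runif(n * n * 5, 0.5, 1), c(n, n, 5)))
  km <- localKMap(s1, s2, R, "cossq")
  expect_equal(dim(km@values), c(7L, 7L))
  expect_equal(diff(km@centerX)[1], R / a)
  expect_equal(dim(km@full), c(n, n))
  expect_error(localKMap(stackFromArray(array(1, c(20, 20, 5))),
                         stackFromArray(array(1, c(20, 20, 5))), R),
               "smaller than 3R")
})

test_that("each subregion value equals a standalone K with injected global means", {
  set.seed(42)
  R <- 100; a <- 10; n <- 50
  s1 <- stackFromArray(array(runif(n * n * 7, 0, 2), c(n, n, 7)))
  s2 <- stackFromArray(array(runif(n * n * 7, 0, 2), c(n, n, 7)))
  km <- localKMap(s1, s2, R)
  dphi <- pi / 7
  means <- c(mean(dphi * rowSums(s1@values, dims = 2)),
             mean(dphi * rowSums(s2@values, dims = 2)))
  side <- 3 * R / a
  for (idx in list(c(1, 1), c(2, 3))) {
    ry <- ((idx[1] - 1) * R / a + 1):((idx[1] - 1) * R / a + side)
    rx <- ((idx[2] - 1) * R / a + 1):((idx[2] - 1) * R / a + side)
    c1 <- stackFromArray(s1@values[ry, rx, , drop = FALSE])
    c2 <- stackFromArray(s2@values[ry, rx, , drop = FALSE])
    ref <- kValue(kParallel(crossCorrelate(c1, c2, lagMax = R,
                                           means = means), R))
    expect_equal(km@values[idx[1], idx[2]], ref, tolerance = 1e-8)
  }
})

test_that("perpendicular grids score negative with cos2phi and positive with cos^2", {
  fov <- 1200
  mkGrid <- function(angle) {
    pts <- lapply(seq(150, 1050, by = 300), function(off) {
      tt <- seq(-600, 600, by = 2)
      if (angle == 0) cbind(tt + fov / 2, rep(off, length(tt)))
      else cbind(rep(off, length(tt)), tt + fov / 2)
    })
    p <- do.call(rbind, pts)
    keep <- p[, 1] >= 0 & p[, 1] < fov & p[, 2] >= 0 & p[, 2] < fov
    p <- p[keep, ]
    LocalizationSet(p[, 1], p[, 2], rep(5, nrow(p)), rep(1000, nrow(p)),
                    seq_len(nrow(p)))
  }
  ext <- c(0, fov, 0, fov)
  oa1 <- suppressWarnings(orientationAnalysis(mkGrid(0), 10, ext, 100, 11))
  oa2 <- suppressWarnings(orientationAnalysis(mkGrid(pi / 2), 10, ext, 100,
                                              11, bank = oa1$bank))
  kPerp <- localKMap(oa1$stack, oa2$stack, 200, "cos2phi")
  kSq <- localKMap(oa1$stack, oa2$stack, 200, "cossq")
  # crossings dominate every subregion here
  expect_lt(max(kPerp@values), 0)
  expect_gt(max(kSq@values), 0)
})

test_that("fast map vanishes for constant stacks and ranks like the exact map", {
  cst <- stackFromArray(array(2, c(60, 60, 9)))
  fm <- fastLocalK(cst, cst, 150)
  expect_lt(max(abs(fm@full)), 1e-10)

  set.seed(43)
  sim <- simulateDataset("parallel", nFilaments = 60L, nFluorophores = 3000,
                         fov = 2000)
  ext <- c(0, 2000, 0, 2000)
  oa1 <- suppressWarnings(orientationAnalysis(sim$locs1, 10, ext, 100, 11))
  oa2 <- suppressWarnings(orientationAnalysis(sim$locs2, 10, ext, 100, 11,
                                              bank = oa1$bank))
  ex <- localKMap(oa1$stack, oa2$stack, 200)
  fa <- fastLocalK(oa1$stack, oa2$stack, 200)
  atCenters <- fa@full[round(ex@centerY), round(ex@centerX)]
  rho <- cor(as.vector(ex@values), as.vector(atCenters), method = "spearman")
  # regression bound frozen from the reference calibration run
  expect_gt(rho, 0.70)
})

test_that("overlay rendering clips and scales the blue channel as specified", {
  vals <- matrix(0:99, 10, 10)
  km <- new("LocalKMap", values = matrix(numeric(0), 0, 0),
            centerX = numeric(0), centerY = numeric(0),
            full = vals, R = 100, weight = "cos2phi", means = c(1, 1))
  img <- new("PixelImage", values = matrix(1, 10, 10), binSize = 10,
             origin = c(0, 0), nDropped = 0L)
  rgb <- renderOverlay(img, img, km, clipFraction = 0.03, channelClip = 0)
  blue <- rgb[, , 3]
  q97 <- quantile(vals, 0.97, names = FALSE)
  expect_true(all(blue[vals >= q97] == 1))
  expect_true(all(blue[vals < q97] < 1))
  # all-negative map gives an all-zero blue channel
  km@full <- -vals - 1
  rgbNeg <- renderOverlay(img, img, km, clipFraction = 0.03)
  expect_true(all(rgbNeg[, , 3] == 0))
  # clipFraction 0 is pure max scaling
  km@full <- vals
  rgb0 <- renderOverlay(img, img, km, clipFraction = 0)
  expect_equal(max(rgb0[, , 3]), 1)
  expect_equal(rgb0[, , 3], vals / 99)
  # PNG writing round-trips
  f <- tempfile(fileext = ".png")
  renderOverlay(img, img, km, path = f)
  expect_true(file.exists(f))
  expect_equal(dim(png::readPNG(f)), c(10, 10, 3))
})
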