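test_that("binning follows the half-open floor convention and conserves counts", {
  locs <- LocalizationSet(c(5, 15), c(5, 5), c(10, 10), c(1000, 1000), 1:2)
  img <- binLocalizations(locs, 10, extent = c(0, 20, 0, 10))
  expect_equal(dim(values(img)), c(1L, 2L))
  expect_equal(as.vector(values(img)), c(1, 1))

  empty <- LocalizationSet(numeric(0), numeric(0), numeric(0), numeric(0),
                           integer(0))
  img0 <- binLocalizations(empty, 10, extent = c(0, 100, 0, 100))
  expect_equal(sum(values(img0)), 0)

  set.seed(42)
  n <- 1e4
  big <- uniformLocs(n, 4000)
  imgN <- suppressWarnings(binLocalizations(big, 10, c(0, 4000, 0, 4000)))
  expect_equal(dim(values(imgN)), c(400L, 400L))
  expect_equal(sum(values(imgN)), n)

  # out-of-extent points are dropped and reported
  out <- LocalizationSet(c(5, 150), c(5, 5), c(10, 10), c(1e3, 1e3), 1:2)
  imgD <- binLocalizations(out, 10, extent = c(0, 20, 0, 10))
  expect_equal(imgD@nDropped, 1L)
  expect_equal(sum(values(imgD)), 1)
})

test_that("binning input validation and pixel-size guard", {
  locs <- LocalizationSet(1, 1, 10, 1000, 1L)
  expect_error(binLocalizations(locs, 10, extent = c(0, 0, 0, 10)),
               "empty extent")
  # non-finite coordinates are rejected at construction, naming the record
  expect_error(LocalizationSet(c(1, NaN), c(1, 2), c(5, 5), c(10, 10), 1:2),
               "record")
  bad <- LocalizationSet(c(1, 2), c(1, 2), c(5, 5), c(10, 10), 1:2)
  bad@records$x[2] <- Inf    # direct slot surgery bypasses the validity hook
  expect_error(suppressWarnings(binLocalizations(bad, 10, c(0, 10, 0, 10))),
               "record")
  fine <- LocalizationSet(c(1, 2, 3), c(1, 2, 3), c(2, 2, 2), rep(10, 3), 1:3)
  expect_warning(binLocalizations(fine, 10, c(0, 10, 0, 10)),
                 "1.5 x median precision")
})

test_that("filter bank matches its analytic form", {
  bank <- buildFilterBank(c(64, 64), 10, 100, nO = 9)
  expect_equal(bank@wPhi, pi / 9)
  # peak modulus 2 on the ring q = 1/so at the filter's own angle (analytic)
  for (k in c(1, 4, 9))
    expect_equal(filterResponse(bank, 1 / 100, bank@angles[k], k), 2,
                 tolerance = 1e-6)
  # sampled filters never exceed the analytic maximum and approach it
  expect_lt(max(bank@filters), 2 + 1e-9)
  expect_gt(max(bank@filters), 2 - 0.05)
  # zero DC
  expect_identical(bank@filters[1, 1, ], rep(0, 9))
  expect_equal(filterResponse(bank, 0, 0, 1), 0)
  # angular bandwidth at the study's orientation count
  bank41 <- buildFilterBank(c(16, 16), 10, 200, nO = 41)
  expect_equal(bank41@wPhi, pi / 41, tolerance = 1e-12)
  expect_error(buildFilterBank(c(64, 64), 10, -5), "so")
  expect_error(buildFilterBank(c(64, 64), 10, 100, nO = 1), "nO")
  expect_warning(buildFilterBank(c(64, 64), 10, 15), "resolution")
})

test_that("orientation filtering recovers line orientations", {
  fov <- 1280
  angles <- seq(-85, 80, length.out = 12) * pi / 180
  for (so in c(100, 200, 500)) {
    bank <- NULL
    for (ang in angles) {
      locs <- lineLocs(ang, fov)
      img <- suppressWarnings(binLocalizations(locs, 10, c(0, fov, 0, fov)))
      if (is.null(bank))
        bank <- buildFilterBank(dim(values(img)), 10, so, nO = 41)
      st <- computeOrientationSpace(img, bank)
      A <- Mod(values(st))
      mid <- dim(A)[1] %/% 2
      kbest <- which.max(A[mid, mid, ])
      kexp <- which.min(abs(coorient:::.wrapOrientation(bank@angles - ang)))
      expect_equal(kbest, kexp,
                   label = sprintf("so=%g angle=%.1fdeg", so, ang * 180 / pi))
    }
  }
})

test_that("crossing filaments yield two angular maxima at the crossing", {
  fov <- 1280
  l0 <- localizations(lineLocs(0, fov))
  l90 <- localizations(lineLocs(pi / 2, fov))
  both <- LocalizationSet(c(l0$x, l90$x), c(l0$y, l90$y),
                          c(l0$sigma, l90$sigma),
                          c(l0$photons, l90$photons),
                          seq_len(nrow(l0) + nrow(l90)))
  img <- suppressWarnings(binLocalizations(both, 10, c(0, fov, 0, fov)))
  bank <- buildFilterBank(dim(values(img)), 10, 200, nO = 41)
  st <- computeOrientationSpace(img, bank)
  mid <- dim(values(img))[1] %/% 2
  resp <- Mod(values(st)[mid, mid, ])
  # local maxima on the circular angle grid; the two dominant ones
  nO <- length(resp)
  isMax <- resp > resp[c(nO, 1:(nO - 1))] & resp > resp[c(2:nO, 1)]
  peaks <- bank@angles[isMax][order(resp[isMax], decreasing = TRUE)][1:2]
  expect_lt(min(abs(coorient:::.wrapOrientation(peaks - 0))), bank@wPhi)
  expect_lt(min(abs(coorient:::.wrapOrientation(peaks - pi / 2))), bank@wPhi)
})

test_that("FFT filtering equals brute-force spatial convolution", {
  set.seed(7)
  img <- new("PixelImage", values = matrix(rpois(64 * 64, 0.05), 64),
             binSize = 10, origin = c(0, 0), nDropped = 0L)
  bank <- buildFilterBank(c(64, 64), 10, 100, nO = 5)
  st <- computeOrientationSpace(img, bank)
  for (k in c(1, 3)) {
    ref <- bruteOrientationResponse(img, bank, k)
    got <- values(st)[, , k]
    expect_lt(max(Mod(got - ref)) / max(Mod(ref)), 1e-8)
  }
  # all-zero image gives an all-zero stack
  img0 <- new("PixelImage", values = matrix(0, 64, 64), binSize = 10,
              origin = c(0, 0), nDropped = 0L)
  expect_equal(max(Mod(values(computeOrientationSpace(img0, bank)))), 0)
})

test_that("normalization satisfies the per-pixel angular integral identity", {
  set.seed(8)
  locs <- uniformLocs(500, 640)
  img <- suppressWarnings(binLocalizations(locs, 10, c(0, 640, 0, 640)))
  bank <- buildFilterBank(dim(values(img)), 10, 100, nO = 11)
  st <- normalizeOrientationSpace(computeOrientationSpace(img, bank), img)
  dphi <- pi / 11
  sums <- dphi * rowSums(values(st), dims = 2)
  expect_equal(sums, values(img), tolerance = 1e-12)
  expect_gte(min(values(st)), 0)
  # zero-count pixels are exactly zero across orientations
  zr <- which(values(img) == 0)[1:50]
  for (k in c(1, 6)) expect_identical(unname(values(st)[, , k][zr]),
                                      rep(0, 50))
})

test_that("isotropic pixels fall back to the uniform density I/pi", {
  nO <- 7
  raw <- array(complex(real = 2), c(2, 2, nO))   # flat response everywhere
  stack <- new("OrientationStack", values = raw, kind = "raw", binSize = 10,
               origin = c(0, 0), angles = coorient:::.orientationGrid(nO),
               so = 100)
  img <- new("PixelImage", values = matrix(c(3, 0, 1, 5), 2), binSize = 10,
             origin = c(0, 0), nDropped = 0L)
  stn <- normalizeOrientationSpace(stack, img)
  expect_equal(values(stn)[1, 1, ], rep(3 / pi, nO))
  expect_equal(values(stn)[2, 1, ], rep(0, nO))
  expect_equal(pi / nO * sum(values(stn)[1, 2, ]), 1)
  expect_equal(pi / nO * sum(values(stn)[2, 2, ]), 5)
})

test_that("the fast internal orientation path equals the two-step public path", {
  set.seed(9)
  locs <- uniformLocs(300, 640)
  img <- suppressWarnings(binLocalizations(locs, 10, c(0, 640, 0, 640)))
  bank <- buildFilterBank(dim(values(img)), 10, 100, nO = 9)
  slow <- values(normalizeOrientationSpace(computeOrientationSpace(img, bank),
                                           img))
  fast <- coorient:::.orientNormArr(values(img), bank)
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("orientation grid spans [-pi/2, pi/2)", {
  g <- coorient:::.orientationGrid(41)
  expect_equal(g[1], -pi / 2)
  expect_lt(max(g), pi / 2)
  expect_equal(diff(g)[1], pi / 41)
})

test_that("orientation stacks round-trip through TIFF + JSON sidecar", {
  set.seed(10)
  a <- array(runif(8 * 8 * 5), c(8, 8, 5))
  st <- stackFromArray(a)
  path <- tempfile(fileext = ".tif")
  writeOrientationStack(st, path)
  back <- readOrientationStack(path)
  expect_equal(values(back), values(st), tolerance = 1e-6)
  expect_equal(binSize(back), binSize(st))
  expect_equal(orientationAngles(back), orientationAngles(st))
})
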