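test_that("FFT cross-correlation equals the direct sextuple-loop evaluation", {
  set.seed(21)
  for (nO in c(3, 5)) {
    d <- c(8, 8, nO)
    a1 <- array(sample(0:4, prod(d), replace = TRUE), d)
    a2 <- array(sample(0:4, prod(d), replace = TRUE), d)
    W <- matrix(1, 8, 8); W[1:2, 1:3] <- 0
    s1 <- stackFromArray(a1); s2 <- stackFromArray(a2)
    map <- crossCorrelate(s1, s2, maskROI(W), lagMax = 30)
    ref <- bruteCrossCorrelate(a1, a2, W, 3)
    ok <- !is.na(ref) & !is.na(map@values)
    expect_equal(is.na(ref), is.na(map@values))
    expect_lt(max(abs(map@values[ok] - ref[ok])) / max(abs(ref[ok])), 1e-8)
  }
})

test_that("identical single-line stacks autocorrelate with a peak at zero lag", {
  fov <- 640
  # a finite line segment well inside the field, so overlap loss dominates
  locs <- lineLocs(pi / 6, fov, half = 150)
  oa <- suppressWarnings(orientationAnalysis(locs, 10, c(0, fov, 0, fov),
                                             so = 100, nO = 11))
  map <- crossCorrelate(oa$stack, oa$stack, lagMax = 100)
  pk <- which(map@values == max(map@values, na.rm = TRUE), arr.ind = TRUE)
  nlag <- (dim(map@values)[1] - 1) / 2
  expect_equal(unname(pk[1, 1:2]), c(nlag + 1, nlag + 1))
  expect_equal(map@dphi[pk[1, 3]], 0)
})

test_that("cross-correlation input validation", {
  a <- array(1, c(8, 8, 3))
  s1 <- stackFromArray(a)
  s2 <- stackFromArray(array(1, c(8, 8, 5)))
  expect_error(crossCorrelate(s1, s2, lagMax = 30), "mismatched")
  z <- stackFromArray(array(0, c(8, 8, 3)))
  expect_error(crossCorrelate(s1, z, lagMax = 30), "empty channel")
})

test_that("radial profile averages annuli centered on lag multiples", {
  # constant map stays constant in every populated annulus
  cmap <- constantMap(function(phi) rep(1, length(phi)), nlag = 10, nO = 5)
  prof <- radialProfile(cmap)
  pop <- !is.na(prof$profile)
  expect_true(all(abs(prof$profile[pop] - 1) < 1e-12))

  # mass on the ring 45 <= r < 55 reports only in the 50 nm annulus
  nlag <- 10; nO <- 5
  dg <- coorient:::.dphiGrid(nO)
  rad <- sqrt(outer((-nlag:nlag)^2, (-nlag:nlag)^2, `+`)) * 10
  ring <- rad >= 45 & rad < 55
  vals <- array(0, c(2 * nlag + 1, 2 * nlag + 1, nO))
  for (m in seq_len(nO)) vals[, , m][ring] <- 2
  rmap <- new("CoorientationMap", values = vals,
              valid = matrix(TRUE, 2 * nlag + 1, 2 * nlag + 1),
              dphi = dg$dphi, lagStep = 10, means = c(1, 1), maskSum = 1)
  prof2 <- radialProfile(rmap)
  nz <- which(rowSums(prof2$profile, na.rm = TRUE) > 0)
  expect_equal(prof2$r[nz], 50)

  # equality with a per-pixel loop on a random small map
  set.seed(22)
  vr <- array(runif(21 * 21 * 5), c(21, 21, 5))
  rmap2 <- new("CoorientationMap", values = vr,
               valid = matrix(TRUE, 21, 21), dphi = dg$dphi, lagStep = 10,
               means = c(1, 1), maskSum = 1)
  prof3 <- radialProfile(rmap2)
  bin <- round(rad / 10)
  for (m in c(1, 4)) {
    ref <- tapply(vr[, , m], bin, mean)
    got <- prof3$profile[as.integer(names(ref)) + 1, m]
    expect_equal(unname(got), unname(as.numeric(ref)), tolerance = 1e-12)
  }
})

test_that("K closed forms: unit cosine modulation gives 1, constants vanish", {
  mapA <- constantMap(function(phi) 1 + cos(2 * phi))
  expect_equal(kValue(kParallel(mapA, 200)), 1, tolerance = 1e-6)
  mapC <- constantMap(function(phi) rep(3.7, length(phi)))
  expect_equal(kValue(kParallel(mapC, 200)), 0, tolerance = 1e-12)
  # cos^2 weight keeps the co-localization part
  expect_equal(kValue(kParallel(mapC, 200, "cossq")), 3.7, tolerance = 1e-12)
  expect_error(kParallel(mapA, 500), "lag support")
})

test_that("K is linear in the map and obeys the cos^2 Fourier identity", {
  set.seed(23)
  dg <- coorient:::.dphiGrid(41)
  mk <- function() {
    v <- array(runif(41 * 41 * 41), c(41, 41, 41))
    new("CoorientationMap", values = v, valid = matrix(TRUE, 41, 41),
        dphi = dg$dphi, lagStep = 10, means = c(1, 1), maskSum = 1)
  }
  m1 <- mk(); m2 <- mk()
  lin <- function(a, b) {
    m3 <- m1
    m3@values <- a * m1@values + b * m2@values
    m3
  }
  K1 <- kValue(kParallel(m1, 150)); K2 <- kValue(kParallel(m2, 150))
  K3 <- kValue(kParallel(lin(2.5, -0.75), 150))
  expect_equal(K3, 2.5 * K1 - 0.75 * K2, tolerance = 1e-12)
  # cos^2 phi = (1 + cos 2 phi)/2: K_cossq = K_cos2phi/2 + colocalization
  Kcs <- kValue(kParallel(m1, 150, "cossq"))
  Kcc <- kValue(kParallel(m1, 150, function(phi) rep(1, length(phi))))
  expect_equal(Kcs, K1 / 2 + Kcc / 2, tolerance = 1e-12)
})

test_that("independent homogeneous channels give c near 1 (single seed)", {
  set.seed(24)
  fov <- 2000
  l1 <- uniformLocs(5000, fov, "ch1")
  l2 <- uniformLocs(5000, fov, "ch2")
  oa1 <- suppressWarnings(orientationAnalysis(l1, 10, c(0, fov, 0, fov),
                                              200, 21))
  oa2 <- suppressWarnings(orientationAnalysis(l2, 10, c(0, fov, 0, fov),
                                              200, 21, bank = oa1$bank))
  map <- crossCorrelate(oa1$stack, oa2$stack, lagMax = 400)
  expect_equal(mean(map@values, na.rm = TRUE), 1, tolerance = 0.05)
})

test_that("invalid lags are flagged and excluded rather than zero-filled", {
  set.seed(25)
  a <- array(runif(12 * 12 * 3, 1, 2), c(12, 12, 3))
  W <- matrix(0, 12, 12); W[1:3, 1:3] <- 1   # tiny ROI: large lags invalid
  s <- stackFromArray(a)
  map <- crossCorrelate(s, s, maskROI(W), lagMax = 80)
  expect_true(any(!map@valid))
  expect_true(all(is.na(map@values[, , 1][!map@valid])))
  expect_true(all(map@values[, , 1][map@valid] >= 0))
})
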