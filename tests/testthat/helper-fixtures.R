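# Shared fixtures and independent oracles for the test suite.

# Uniform random localization field.
uniformLocs <- function(n, fov, channel = "ch", sigma = 5) {
  LocalizationSet(runif(n, 0, fov), runif(n, 0, fov), rep(sigma, n),
                  rep(1000, n), seq_len(n), channel = channel)
}

# Localizations along a straight line through the field center.
lineLocs <- function(angle, fov, spacing = 2, sigma = 5, channel = "ch",
                     half = fov / sqrt(2)) {
  tt <- seq(-half, half, by = spacing)
  LocalizationSet(fov / 2 + tt * cos(angle), fov / 2 + tt * sin(angle),
                  rep(sigma, length(tt)), rep(1000, length(tt)),
                  seq_along(tt), channel = channel)
}

# Build a normalized OrientationStack directly from an array (unit test glue).
stackFromArray <- function(a, binSize = 10, so = 100) {
  new("OrientationStack", values = a, kind = "normalized", binSize = binSize,
      origin = c(0, 0), angles = coorient:::.orientationGrid(dim(a)[3]),
      so = so)
}

# Constant-c CoorientationMap over a (2*nlag+1)^2 lag window.
constantMap <- function(cfun, nlag = 20, nO = 41, lagStep = 10) {
  dg <- coorient:::.dphiGrid(nO)
  vals <- array(rep(cfun(dg$dphi), each = (2 * nlag + 1)^2),
                c(2 * nlag + 1, 2 * nlag + 1, nO))
  new("CoorientationMap", values = vals,
      valid = matrix(TRUE, 2 * nlag + 1, 2 * nlag + 1), dphi = dg$dphi,
      lagStep = lagStep, means = c(1, 1), maskSum = 1)
}

# Brute-force generalized cross-correlation: direct evaluation of the
# defining sums (independent of the FFT implementation).
bruteCrossCorrelate <- function(a1, a2, W, nlag) {
  d <- dim(a1)
  nO <- d[3]
  dphiBin <- pi / nO
  I1 <- dphiBin * rowSums(a1, dims = 2)
  I2 <- dphiBin * rowSums(a2, dims = 2)
  m1 <- sum(W * I1) / sum(W)
  m2 <- sum(W * I2) / sum(W)
  lags <- (-nlag):nlag
  cc <- array(NA_real_, c(length(lags), length(lags), nO))
  for (a in seq_along(lags)) for (b in seq_along(lags)) {
    di <- lags[a]; dj <- lags[b]
    num <- numeric(nO); cnt <- 0
    for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
      y2 <- y + di; x2 <- x + dj
      if (y2 >= 1 && y2 <= d[1] && x2 >= 1 && x2 <= d[2] &&
          W[y, x] == 1 && W[y2, x2] == 1) {
        cnt <- cnt + 1
        for (m in 0:(nO - 1)) {
          s <- 0
          for (k in seq_len(nO)) {
            k2 <- ((k - 1 + m) %% nO) + 1
            s <- s + a1[y, x, k] * a2[y2, x2, k2]
          }
          num[m + 1] <- num[m + 1] + s
        }
      }
    }
    if (cnt > 0) cc[a, b, ] <- pi * dphiBin * num / (m1 * m2 * cnt)
  }
  # reorder the dphi axis to match crossCorrelate (ascending dphi)
  perm <- coorient:::.dphiGrid(nO)$perm
  cc[, , perm, drop = FALSE]
}

# Brute-force spatial convolution of a padded image with the k-th filter
# kernel of a bank (circular convolution on the padded grid, then crop).
bruteOrientationResponse <- function(img, bank, k) {
  py <- bank@paddedDim[1]; px <- bank@paddedDim[2]
  pad <- coorient:::.padSpatial(values(img), py, px)
  kern <- fft(bank@filters[, , k], inverse = TRUE) / (py * px)
  out <- matrix(complex(real = 0), py, px)
  nzi <- which(pad != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nzi))) {
    y <- nzi[r, 1]; x <- nzi[r, 2]
    w <- pad[y, x]
    # kern index for displacement (dy, dx) = ((y'-y) mod py) + 1
    rows <- ((seq_len(py) - y) %% py) + 1
    cols <- ((seq_len(px) - x) %% px) + 1
    out <- out + w * kern[rows, cols]
  }
  out[seq_len(dim(values(img))[1]), seq_len(dim(values(img))[2])]
}

# Scaled null dataset used by the calibration suite: independent channels,
# 50 filaments each, 2 um field, 2500 expected fluorophores per channel.
nullDataset <- function(seed) {
  set.seed(seed)
  simulateDataset("independent", nFilaments = 50L, nFluorophores = 2500,
                  fov = 2000)
}

# One rep of the null-calibration study (reduced scale, nTheta = 25,
# nO = 21); returns K, sigma_K^2 and p.
nullRep <- function(seed) {
  sim <- nullDataset(seed)
  test <- suppressWarnings(significanceTest(
    sim$locs1, sim$locs2, circleROI(c(1000, 1000), 1000), c(0, 2000, 0, 2000),
    R = 200, nTheta = 25L, binSize = 10, so = 200, nO = 21L))
  c(K = kValue(test), sigma2 = sigma2Of(test), p = pValueOf(test))
}

# Cached batch of null reps shared by the calibration criteria.
nullBatch <- local({
  cache <- NULL
  function(n = 50L) {
    if (is.null(cache) || nrow(cache) < n)
      cache <<- t(vapply(seq_len(n), function(i) nullRep(20000L + i),
                         numeric(3)))
    cache[seq_len(n), , drop = FALSE]
  }
})
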