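#' Construct a simulation configuration
#'
#' Bundles the study conditions for the two-channel filament simulator; see
#' [SimulationConfig-class] for the meaning of each parameter. Defaults:
#' 4 um field, wormlike chains of 10^4 segments of 1 nm with persistence
#' length 5 um, parallel companions at 50 nm, 10^4 expected fluorophores per
#' channel, antibody jitter 5 nm FWHM, blink count min(Poisson(25),
#' Geometric(11)), geometric photons with mean 2000, background 1
#' photon/pixel, PSF width 1.38 camera pixels with 2% spread, camera pixel
#' 100 nm.
#'
#' @param fov field of view in nm.
#' @param nFilaments number of filaments in channel 1.
#' @param xi channel-1 persistence length (nm).
#' @param mode channel-2 derivation mode: `"parallel"`, `"independent"` or
#'   `"twisted"`.
#' @param d parallel offset (nm).
#' @param xi2 independent-mode persistence length (nm).
#' @param dmax,period twisted-mode maximum perpendicular offset and contour
#'   period (nm).
#' @param nFluorophores expected number of fluorophores per channel.
#' @param jitterFwhm antibody jitter FWHM (nm).
#' @param meanBlinkPoisson,meanBlinkGeometric blink-count means.
#' @param meanPhotons mean signal photons per localization.
#' @param meanBackground mean background photons per pixel.
#' @param psfWidthPx,psfWidthRelSd PSF width (camera px) and relative SD.
#' @param cameraPixel camera pixel size (nm).
#' @param segLen,nSegments filament discretization.
#' @param densityBin,densityBlurFwhm filament density rendering (nm).
#' @param nFrames camera frames available for blink trains.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(fov = 4000, nFilaments = 200L, xi = 5000,
                             mode = "parallel", d = 50, xi2 = 1000,
                             dmax = 50, period = 300, nFluorophores = 1e4,
                             jitterFwhm = 5, meanBlinkPoisson = 25,
                             meanBlinkGeometric = 11, meanPhotons = 2000,
                             meanBackground = 1, psfWidthPx = 1.38,
                             psfWidthRelSd = 0.02, cameraPixel = 100,
                             segLen = 1, nSegments = 10000L, densityBin = 5,
                             densityBlurFwhm = 5, nFrames = 10000L) {
  new("SimulationConfig", fov = fov, nFilaments = as.integer(nFilaments),
      xi = xi, mode = mode, d = d, xi2 = xi2, dmax = dmax, period = period,
      nFluorophores = nFluorophores, jitterFwhm = jitterFwhm,
      meanBlinkPoisson = meanBlinkPoisson,
      meanBlinkGeometric = meanBlinkGeometric, meanPhotons = meanPhotons,
      meanBackground = meanBackground, psfWidthPx = psfWidthPx,
      psfWidthRelSd = psfWidthRelSd, cameraPixel = cameraPixel,
      segLen = segLen, nSegments = as.integer(nSegments),
      densityBin = densityBin, densityBlurFwhm = densityBlurFwhm,
      nFrames = as.integer(nFrames))
}

#' Simulate a 2D wormlike-chain filament
#'
#' Grows a Kratky-Porod chain of `nSegments` segments of length `segLen`
#' symmetrically from a central segment: the central segment's midpoint is
#' placed uniformly in a disc of radius `placementRadius` about `center`,
#' its orientation is uniform in `(-pi, pi]`, and every turn between
#' subsequent segments is drawn from `Normal(0, sqrt(segLen/xi))`, the 2D
#' wormlike-chain discretization for persistence length `xi` (tangent
#' correlations decay as `exp(-s/(2*xi))` in 2D).
#'
#' @param xi persistence length in nm.
#' @param nSegments number of segments (vertex count is `nSegments + 1`).
#' @param segLen segment length in nm (default 1).
#' @param center disc center for the central-segment placement (nm).
#' @param placementRadius placement disc radius (nm); the convention
#'   `FOV/sqrt(2) + L/2` guarantees homogeneous coverage of a square field.
#' @return `nSegments + 1` x 2 matrix of vertex coordinates.
#' @export
simulateWormlikeChain <- function(xi, nSegments = 10000L, segLen = 1,
                                  center = c(0, 0),
                                  placementRadius = 0) {
  if (xi <= 0) .stopf("xi must be > 0")
  n <- as.integer(nSegments)
  if (placementRadius > 0) {
    u <- runif(1); ang <- runif(1, 0, 2 * pi)
    mid <- center + placementRadius * sqrt(u) * c(cos(ang), sin(ang))
  } else mid <- center
  theta0 <- runif(1, -pi, pi)
  sdTurn <- sqrt(segLen / xi)
  m <- (n + 1L) %/% 2L                       # index of the central segment
  turns <- rnorm(n - 1L, 0, sdTurn)
  # tangent angle per segment, diffusing outward from segment m
  t <- numeric(n)
  t[m] <- theta0
  if (m < n) t[(m + 1L):n] <- theta0 + cumsum(turns[m:(n - 1L)])
  if (m > 1L) t[(m - 1L):1L] <- theta0 - cumsum(turns[(m - 1L):1L])
  dx <- segLen * cos(t); dy <- segLen * sin(t)
  vx <- c(0, cumsum(dx)); vy <- c(0, cumsum(dy))
  # translate so the central segment's midpoint sits at the placement point
  cx <- (vx[m] + vx[m + 1L]) / 2; cy <- (vy[m] + vy[m + 1L]) / 2
  cbind(x = vx - cx + mid[1L], y = vy - cy + mid[2L])
}

#' Simulate a channel-1 filament set
#'
#' @param cfg a [SimulationConfig-class].
#' @return a [FilamentSet-class].
#' @export
simulateFilaments <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  L <- cfg@nSegments * cfg@segLen
  radius <- cfg@fov / sqrt(2) + L / 2
  center <- c(cfg@fov / 2, cfg@fov / 2)
  verts <- lapply(seq_len(cfg@nFilaments), function(i)
    simulateWormlikeChain(cfg@xi, cfg@nSegments, cfg@segLen, center, radius))
  new("FilamentSet", vertices = verts, segLen = cfg@segLen, xi = cfg@xi)
}

# Per-vertex unit tangents of a polyline (central differences, one-sided at
# the ends) and the corresponding left normals.
.polylineNormals <- function(v) {
  n <- nrow(v)
  tx <- c(v[2L, 1L] - v[1L, 1L],
          v[3:n, 1L] - v[1:(n - 2L), 1L],
          v[n, 1L] - v[n - 1L, 1L])
  ty <- c(v[2L, 2L] - v[1L, 2L],
          v[3:n, 2L] - v[1:(n - 2L), 2L],
          v[n, 2L] - v[n - 1L, 2L])
  len <- sqrt(tx^2 + ty^2)
  cbind(-ty / len, tx / len)
}

#' Derive the channel-2 filament set
#'
#' Produces the second color channel's filaments from the first according to
#' the configured mode: `"parallel"` displaces each filament by a fixed
#' distance along its local normal (consistent side per filament);
#' `"twisted"` displaces each vertex along the local normal by
#' `dmax * sin(2*pi*s/period + phase)` with `s` the contour distance and a
#' random phase per filament, so the companions appear twisted around the
#' originals; `"independent"` simulates fresh chains with persistence length
#' `xi2`.
#'
#' @param filaments channel-1 [FilamentSet-class].
#' @param cfg a [SimulationConfig-class].
#' @return a [FilamentSet-class] for channel 2.
#' @export
deriveChannel2 <- function(filaments, cfg) {
  stopifnot(is(filaments, "FilamentSet"), is(cfg, "SimulationConfig"))
  mode <- cfg@mode
  if (mode == "independent") {
    cfg2 <- cfg
    cfg2@xi <- cfg@xi2
    return(simulateFilaments(cfg2))
  }
  verts <- lapply(filaments@vertices, function(v) {
    nrm <- .polylineNormals(v)
    if (mode == "parallel") {
      v + cfg@d * nrm
    } else if (mode == "twisted") {
      s <- (seq_len(nrow(v)) - 1L) * filaments@segLen
      phase <- runif(1, 0, 2 * pi)
      off <- cfg@dmax * sin(2 * pi * s / cfg@period + phase)
      v + off * nrm
    } else .stopf("unknown channel-2 mode '%s'", mode)
  })
  new("FilamentSet", vertices = verts, segLen = filaments@segLen,
      xi = filaments@xi)
}

# Gaussian blur of a matrix by FFT on a padded grid; mass-preserving up to
# boundary truncation of the (normalized) kernel.
.gaussianBlur <- function(img, sigmaPx) {
  if (sigmaPx <= 0) return(img)
  d <- dim(img)
  pad <- as.integer(ceiling(4 * sigmaPx)) + 1L
  py <- .goodSize(d[1L] + pad); px <- .goodSize(d[2L] + pad)
  gy <- stats::dnorm(.lagValues(py), 0, sigmaPx)
  gx <- stats::dnorm(.lagValues(px), 0, sigmaPx)
  kern <- outer(gy, gx)
  kern <- kern / sum(kern)
  out <- Re(fft(fft(.padSpatial(img, py, px)) * fft(kern), inverse = TRUE)) /
    (py * px)
  out[seq_len(d[1L]), seq_len(d[2L])]
}

# Signed lag value of each fft index: 0, 1, ..., -1.
.lagValues <- function(n) {
  k <- 0:(n - 1L)
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k
}

#' Render a filament set as a continuous density image
#'
#' Counts filament vertices (segment connecting points) in square bins and
#' convolves with a Gaussian kernel to account for the finite filament
#' width. Total mass equals the number of in-extent vertices, up to kernel
#' truncation at the image boundary.
#'
#' @param filaments a [FilamentSet-class].
#' @param bin bin size in nm (default 5).
#' @param blurFwhm Gaussian blur FWHM in nm (default 5).
#' @param extent `c(xmin, xmax, ymin, ymax)` in nm.
#' @return a [PixelImage-class] (continuous density).
#' @export
renderFilamentDensity <- function(filaments, bin = 5, blurFwhm = 5, extent) {
  stopifnot(is(filaments, "FilamentSet"))
  allv <- do.call(rbind, filaments@vertices)
  nx <- as.integer(ceiling((extent[2L] - extent[1L]) / bin - 1e-9))
  ny <- as.integer(ceiling((extent[4L] - extent[3L]) / bin - 1e-9))
  ix <- floor((allv[, 1L] - extent[1L]) / bin) + 1
  iy <- floor((allv[, 2L] - extent[3L]) / bin) + 1
  keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  img <- matrix(tabulate((ix[keep] - 1) * ny + iy[keep], nbins = nx * ny),
                ny, nx)
  img <- .gaussianBlur(img, .fwhmToSigma(blurFwhm) / bin)
  img[img < 0] <- 0
  new("PixelImage", values = img, binSize = bin,
      origin = c(extent[1L], extent[3L]),
      nDropped = as.integer(sum(!keep)))
}

#' Sample fluorophore positions from a density image
#'
#' Draws a Poisson-distributed number of fluorophores with spatial density
#' proportional to the pixel values (uniform placement within a pixel), then
#' jitters each position isotropically with a Gaussian of the given FWHM to
#' account for the antibody linker size.
#'
#' @param density a non-negative [PixelImage-class]; must not be all zero.
#' @param nExpected expected fluorophore count.
#' @param jitterFwhm jitter FWHM in nm (default 5).
#' @return n x 2 matrix of positions (nm).
#' @export
sampleFluorophores <- function(density, nExpected, jitterFwhm = 5) {
  stopifnot(is(density, "PixelImage"))
  v <- values(density)
  tot <- sum(v)
  if (tot <= 0) .stopf("all-zero density")
  n <- rpois(1L, nExpected)
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  d <- dim(v)
  idx <- sample.int(length(v), n, replace = TRUE, prob = as.vector(v))
  iy <- (idx - 1L) %% d[1L] + 1L
  ix <- (idx - 1L) %/% d[1L] + 1L
  b <- binSize(density)
  x <- gridOrigin(density)[1L] + (ix - 1L + runif(n)) * b
  y <- gridOrigin(density)[2L] + (iy - 1L + runif(n)) * b
  sj <- .fwhmToSigma(jitterFwhm)
  cbind(x = x + rnorm(n, 0, sj), y = y + rnorm(n, 0, sj))
}

# Localization precision (nm) from the maximum-likelihood expression for a
# Gaussian PSF fit: sigma^2 = (sa^2 / N) * (16/9 + 8*pi*sa^2*b / (N*a^2)),
# with sa^2 = sigma_psf^2 + a^2/12 (pixelation-corrected PSF width), N the
# signal photons, b background photons per pixel, a the camera pixel size.
# Excess-noise factor omitted.
.localizationPrecision <- function(nPhotons, background, psfSigmaNm, pixelNm) {
  sa2 <- psfSigmaNm^2 + pixelNm^2 / 12
  sqrt(sa2 / nPhotons * (16 / 9 + 8 * pi * sa2 * background /
                           (nPhotons * pixelNm^2)))
}

#' Simulate localization events for a set of fluorophores
#'
#' Each fluorophore blinks `M = min(M_poisson, M_geometric)` times, with
#' `M_poisson ~ Poisson(meanBlinkPoisson)` and `M_geometric` geometric on
#' `{1, 2, ...}` with mean `meanBlinkGeometric` (a fluorophore with
#' `M_poisson = 0` is never localized). Each localization draws signal
#' photons from a geometric distribution on `{1, 2, ...}` with mean
#' `meanPhotons`, a background level as the average of 9 x 9 Poisson values
#' with mean `meanBackground`, and a PSF width `Normal(psfWidthPx,
#' psfWidthRelSd * psfWidthPx)` camera pixels; the localization precision
#' sigma follows from the maximum-likelihood precision expression for a
#' pixelated Gaussian PSF (see the package vignette for the formula), and
#' the recorded position is the fluorophore position displaced by
#' `Normal(0, sigma)` per axis. Blink trains occupy consecutive camera
#' frames from a random start frame.
#'
#' @param fluorophores n x 2 matrix of positions (nm).
#' @param cfg a [SimulationConfig-class].
#' @param channel channel label.
#' @return a [LocalizationSet-class] with ground-truth `fluorophore` ids.
#' @export
simulateLocalizations <- function(fluorophores, cfg, channel = "ch") {
  stopifnot(is(cfg, "SimulationConfig"))
  nF <- nrow(fluorophores)
  if (nF == 0L)
    return(LocalizationSet(numeric(0), numeric(0), numeric(0), numeric(0),
                           integer(0), channel = channel,
                           fluorophore = integer(0)))
  mPois <- rpois(nF, cfg@meanBlinkPoisson)
  mGeo <- rgeom(nF, 1 / cfg@meanBlinkGeometric) + 1L
  M <- pmin(mPois, mGeo)
  keep <- M > 0L
  idx <- rep.int(which(keep), M[keep])
  nL <- length(idx)
  if (nL == 0L)
    return(LocalizationSet(numeric(0), numeric(0), numeric(0), numeric(0),
                           integer(0), channel = channel,
                           fluorophore = integer(0)))
  nPh <- rgeom(nL, 1 / cfg@meanPhotons) + 1
  bg <- colMeans(matrix(rpois(81L * nL, cfg@meanBackground), 81L, nL))
  sa <- rnorm(nL, cfg@psfWidthPx, cfg@psfWidthRelSd * cfg@psfWidthPx)
  sigma <- .localizationPrecision(nPh, bg, sa * cfg@cameraPixel,
                                  cfg@cameraPixel)
  x <- fluorophores[idx, 1L] + rnorm(nL, 0, sigma)
  y <- fluorophores[idx, 2L] + rnorm(nL, 0, sigma)
  starts <- sample.int(cfg@nFrames, nF, replace = TRUE)
  frame <- starts[idx] + sequence(M[keep]) - 1L
  LocalizationSet(x, y, sigma, nPh, frame, channel = channel,
                  fluorophore = idx)
}

#' Render localizations as Gaussian blobs
#'
#' Splats each localization as a unit-mass Gaussian with standard deviation
#' equal to its localization precision; the total mass equals the number of
#' localizations up to boundary truncation. Localizations are grouped into
#' precision quantile classes and each class is rendered by FFT convolution.
#'
#' @param locs a [LocalizationSet-class] with precisions present.
#' @param bin bin size in nm.
#' @param extent `c(xmin, xmax, ymin, ymax)` in nm.
#' @param nClasses number of precision classes (default 12).
#' @return a [PixelImage-class].
#' @export
renderGaussianBlobs <- function(locs, bin = 10, extent = NULL, nClasses = 12L) {
  stopifnot(is(locs, "LocalizationSet"))
  r <- localizations(locs)
  if (any(!is.finite(r$sigma))) .stopf("missing precision for some records")
  if (is.null(extent))
    extent <- c(min(r$x), max(r$x) + bin, min(r$y), max(r$y) + bin)
  nx <- as.integer(ceiling((extent[2L] - extent[1L]) / bin - 1e-9))
  ny <- as.integer(ceiling((extent[4L] - extent[3L]) / bin - 1e-9))
  out <- matrix(0, ny, nx)
  if (nrow(r)) {
    cls <- if (nrow(r) > 1L)
      cut(r$sigma, breaks = unique(quantile(r$sigma,
                                            probs = seq(0, 1, length.out = nClasses + 1L))),
          include.lowest = TRUE)
      else factor(1)
    for (g in levels(cls)) {
      sub <- r[cls == g, , drop = FALSE]
      if (!nrow(sub)) next
      ix <- floor((sub$x - extent[1L]) / bin) + 1
      iy <- floor((sub$y - extent[3L]) / bin) + 1
      keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
      if (!any(keep)) next
      h <- matrix(tabulate((ix[keep] - 1) * ny + iy[keep], nbins = nx * ny),
                  ny, nx)
      out <- out + .gaussianBlur(h, mean(sub$sigma) / bin)
    }
  }
  out[out < 0] <- 0
  new("PixelImage", values = out, binSize = bin,
      origin = c(extent[1L], extent[3L]), nDropped = 0L)
}

#' Simulate a complete two-channel localization dataset
#'
#' Runs the full generative model: channel-1 wormlike chains, channel-2
#' derivation, filament density rendering, fluorophore sampling and the
#' localization (blinking/precision) model for both channels. Presets
#' reproduce the package's three validation scenarios:
#' \describe{
#'   \item{`"parallel"`}{200 filaments (xi = 5 um) in a 4 um field, each
#'     accompanied at a fixed 50 nm perpendicular offset; 10^4 expected
#'     fluorophores per channel.}
#'   \item{`"independent"`}{channel 2 simulated independently with
#'     xi = 1 um; otherwise as `"parallel"`.}
#'   \item{`"twisted"`}{50 filaments, companions twisted with 50 nm maximum
#'     separation and a 300 nm period; 5000 expected fluorophores per
#'     channel.}
#' }
#'
#' @param preset `"parallel"`, `"independent"` or `"twisted"`.
#' @param seed optional RNG seed for full reproducibility.
#' @param ... overrides passed to [simulationConfig()] on top of the preset.
#' @return list with `locs1`, `locs2` ([LocalizationSet-class]),
#'   `filaments1`, `filaments2` ([FilamentSet-class]), and `config`.
#' @examples
#' \donttest{
#' sim <- simulateDataset("parallel", seed = 1, nFilaments = 5,
#'                        nFluorophores = 200)
#' nLocalizations(sim$locs1)
#' }
#' @export
simulateDataset <- function(preset = c("parallel", "independent", "twisted"),
                            seed = NULL, ...) {
  preset <- match.arg(preset)
  if (!is.null(seed)) set.seed(seed)
  base <- switch(preset,
    parallel = list(mode = "parallel", nFilaments = 200L, nFluorophores = 1e4),
    independent = list(mode = "independent", nFilaments = 200L,
                       nFluorophores = 1e4, xi2 = 1000),
    twisted = list(mode = "twisted", nFilaments = 50L, nFluorophores = 5000,
                   dmax = 50, period = 300))
  cfg <- do.call(simulationConfig, utils::modifyList(base, list(...)))
  extent <- c(0, cfg@fov, 0, cfg@fov)
  fil1 <- simulateFilaments(cfg)
  fil2 <- deriveChannel2(fil1, cfg)
  den1 <- renderFilamentDensity(fil1, cfg@densityBin, cfg@densityBlurFwhm,
                                extent)
  den2 <- renderFilamentDensity(fil2, cfg@densityBin, cfg@densityBlurFwhm,
                                extent)
  fl1 <- sampleFluorophores(den1, cfg@nFluorophores, cfg@jitterFwhm)
  fl2 <- sampleFluorophores(den2, cfg@nFluorophores, cfg@jitterFwhm)
  list(locs1 = simulateLocalizations(fl1, cfg, channel = "ch1"),
       locs2 = simulateLocalizations(fl2, cfg, channel = "ch2"),
       filaments1 = fil1, filaments2 = fil2, config = cfg)
}
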