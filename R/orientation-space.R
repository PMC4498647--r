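#' Build a bank of orientation-selective Fourier filters
#'
#' Constructs the Fourier-domain filter stack used for orientation-space
#' analysis. Each filter is the product of an angular Gaussian of bandwidth
#' `wPhi = pi/nO` around its nominal orientation and a radial band-pass
#' profile `(q*so)^(1/(wq^2*so^2)) * exp(-(q^2*so^2 - 1)/(2*wq^2*so^2))`
#' which peaks with value 1 at `q = 1/so`, so the maximum filter modulus over
#' the frequency plane is the prefactor 2, attained on the ring `q = 1/so` at
#' the filter's orientation. The DC component is exactly zero.
#'
#' The angular coordinate `phiQ` of a wavevector is taken as the orientation
#' of the image structure it evidences, i.e. perpendicular to the wavevector,
#' so the filter labelled `phi_k` responds maximally to line-like structures
#' oriented at `phi_k`. A single angular lobe is used (no Hermitian mirror at
#' `phiQ + pi`), so spatial responses are complex; downstream analysis uses
#' their modulus, making the lobe convention immaterial.
#'
#' Filters are sampled on the FFT frequency grid of the zero-padded image:
#' the image is padded by `max(3*so, 3/wq)` (in nm) of pixels per side to
#' suppress periodic wrap-around of the filter kernels.
#'
#' @param imageDim image dimensions `c(rows, cols)` before padding.
#' @param binSize pixel pitch in nm.
#' @param so orientation scale in nm. Warned about if smaller than twice the
#'   pixel pitch (below the image resolution scale).
#' @param nO number of orientations (default 41).
#' @param wq radial bandwidth in 1/nm (default `0.8/so`).
#' @return a [FilterBank-class].
#' @examples
#' bank <- buildFilterBank(c(64, 64), binSize = 10, so = 100, nO = 9)
#' bank@wPhi  # pi/9
#' @export
buildFilterBank <- function(imageDim, binSize, so, nO = 41L, wq = 0.8 / so) {
  if (so <= 0) .stopf("so must be > 0")
  if (nO < 2L) .stopf("nO must be >= 2")
  if (binSize <= 0) .stopf("binSize must be > 0")
  if (so < 2 * binSize)
    .warnf("orientation scale s_o = %.3g nm is below the image resolution scale (2 x %.3g nm bins)",
           so, binSize)
  nO <- as.integer(nO)
  imageDim <- as.integer(imageDim)
  padPx <- as.integer(ceiling(max(3 * so, 3 / wq) / binSize))
  py <- .goodSize(imageDim[1L] + 2L * padPx)
  px <- .goodSize(imageDim[2L] + 2L * padPx)
  qx <- .fftfreq(px, binSize)
  qy <- .fftfreq(py, binSize)
  QX <- matrix(qx, py, px, byrow = TRUE)
  QY <- matrix(qy, py, px)
  q <- sqrt(QX^2 + QY^2)
  # structure orientation evidenced by wavevector (qx, qy): perpendicular
  phiQ <- .wrapAngle(atan2(QY, QX) - pi / 2)
  wPhi <- pi / nO
  beta <- 1 / (wq^2 * so^2)
  radial <- (q * so)^beta * exp(-(q^2 * so^2 - 1) * beta / 2)
  radial[1L, 1L] <- 0   # DC
  angles <- .orientationGrid(nO)
  filters <- array(0, c(py, px, nO))
  plane <- py * px
  for (k in seq_len(nO)) {
    d <- phiQ - angles[k]                 # in (-3*pi/2, 3*pi/2]
    d[d > pi] <- d[d > pi] - 2 * pi
    d[d <= -pi] <- d[d <= -pi] + 2 * pi
    # the angular Gaussian is numerically zero beyond ~8 bandwidths
    nz <- which(abs(d) < 8 * wPhi)
    filters[nz + (k - 1L) * plane] <- 2 * exp(-d[nz]^2 / (2 * wPhi^2)) *
      radial[nz]
  }
  new("FilterBank", so = so, wq = wq, nO = nO, wPhi = wPhi, binSize = binSize,
      imageDim = imageDim, padPx = padPx, paddedDim = c(py, px),
      angles = angles, filters = filters)
}

#' Evaluate the filter transfer function at arbitrary frequencies
#'
#' Closed-form evaluation of a bank filter's Fourier-domain value at
#' frequency magnitude `q` (1/nm) and structure orientation `phiQ` (radians),
#' independent of the FFT grid. Useful for checking analytic properties such
#' as the peak modulus of 2 at `q = 1/so`, `phiQ = phi_k`.
#'
#' @param bank a [FilterBank-class].
#' @param q frequency magnitude(s) in 1/nm.
#' @param phiQ structure orientation(s) in radians.
#' @param k filter index (1-based).
#' @return filter value(s).
#' @export
filterResponse <- function(bank, q, phiQ, k = 1L) {
  stopifnot(is(bank, "FilterBank"))
  beta <- 1 / (bank@wq^2 * bank@so^2)
  radial <- ifelse(q == 0, 0,
                   (q * bank@so)^beta * exp(-(q^2 * bank@so^2 - 1) * beta / 2))
  dphi <- .wrapAngle(phiQ - bank@angles[k])
  2 * exp(-dphi^2 / (2 * bank@wPhi^2)) * radial
}

#' Compute the raw orientation-space representation of an image
#'
#' Convolves a pixel image with every filter of a [FilterBank-class] (FFT,
#' per-orientation multiplication, inverse FFT on the zero-padded grid,
#' cropped back to the image extent), giving the complex response
#' `I(x, phi_k)` that scores the evidence for structures with orientation
#' `phi_k` at each position.
#'
#' @param img a [PixelImage-class].
#' @param bank a [FilterBank-class] built for `dim(values(img))`.
#' @return a raw (complex) [OrientationStack-class].
#' @export
computeOrientationSpace <- function(img, bank) {
  stopifnot(is(img, "PixelImage"), is(bank, "FilterBank"))
  d <- dim(values(img))
  if (!all(d == bank@imageDim))
    .stopf("image is %d x %d but bank was built for %d x %d",
           d[1L], d[2L], bank@imageDim[1L], bank@imageDim[2L])
  if (abs(binSize(img) - bank@binSize) > 1e-9)
    .stopf("image and bank bin sizes differ")
  py <- bank@paddedDim[1L]; px <- bank@paddedDim[2L]
  pad <- .padSpatial(values(img), py, px)
  FI <- fft(pad)
  n <- py * px
  out <- array(complex(real = 0), c(d[1L], d[2L], bank@nO))
  cropIdx <- as.vector(outer(seq_len(d[1L]), (seq_len(d[2L]) - 1L) * py, `+`))
  plane <- d[1L] * d[2L]
  for (k in seq_len(bank@nO)) {
    resp <- fft(FI * bank@filters[, , k], inverse = TRUE) / n
    out[(k - 1L) * plane + seq_len(plane)] <- resp[cropIdx]
  }
  new("OrientationStack", values = out, kind = "raw", binSize = binSize(img),
      origin = gridOrigin(img), angles = bank@angles, so = bank@so)
}

# Fast internal path: histogram counts matrix -> normalized orientation
# density array, without intermediate S4 objects or a complex stack.
# Identical (to floating precision) to computeOrientationSpace followed by
# normalizeOrientationSpace.
.orientNormArr <- function(counts, bank, tol = 1e-9) {
  d <- dim(counts)
  nO <- bank@nO
  py <- bank@paddedDim[1L]; px <- bank@paddedDim[2L]
  FI <- fft(.padSpatial(counts, py, px))
  n <- py * px
  plane <- d[1L] * d[2L]
  cropIdx <- as.vector(outer(seq_len(d[1L]), (seq_len(d[2L]) - 1L) * py, `+`))
  A <- matrix(0, plane, nO)
  for (k in seq_len(nO)) {
    resp <- fft(FI * bank@filters[, , k], inverse = TRUE) / n
    A[, k] <- Mod(resp[cropIdx])
  }
  out <- .normalizeModulus(A, as.vector(counts), nO, tol)
  dim(out) <- c(d[1L], d[2L], nO)
  out
}

# Shared normalization core on the (pixels x orientations) modulus matrix.
.normalizeModulus <- function(A, counts, nO, tol = 1e-9) {
  dphi <- pi / nO
  nr <- nrow(A)
  m <- A[cbind(seq_len(nr), max.col(-A, "first"))]
  S <- rowSums(A)
  denom <- dphi * (S - nO * m)
  iso <- denom <= tol * pmax(dphi * S, .Machine$double.xmin)
  zero <- counts == 0
  scale <- ifelse(zero | iso, 0, counts / denom)
  out <- (A - m) * scale
  uni <- which(iso & !zero)
  if (length(uni)) out[uni, ] <- counts[uni] / pi
  out[out < 0] <- 0
  out
}

#' Normalize an orientation stack to localization densities
#'
#' Converts the raw complex orientation-space response into the normalized
#' per-unit-angle localization density: the modulus is taken, the per-pixel
#' minimum over orientations is subtracted (removing the filters' non-zero
#' response at orientations not present at that pixel), and the result is
#' scaled so that the discrete integral over orientation at each pixel equals
#' the pixel's localization count:
#' \deqn{\tilde I(x,\phi_k) = \frac{|I(x,\phi_k)| - m(x)}
#'   {\Delta\phi \sum_k |I(x,\phi_k)| - \pi m(x)} I(x),}
#' with `m(x) = min_k |I(x, phi_k)|` and `Delta phi = pi/nO`. Pixels with no
#' localizations are all-zero; pixels with an isotropic response (vanishing
#' denominator) get the uniform density `I(x)/pi`, which preserves the
#' integral identity.
#'
#' @param stack a raw [OrientationStack-class].
#' @param img the source histogram [PixelImage-class].
#' @param tol relative flatness tolerance for the isotropic fallback.
#' @return a normalized (real, non-negative) [OrientationStack-class].
#' @export
normalizeOrientationSpace <- function(stack, img, tol = 1e-9) {
  stopifnot(is(stack, "OrientationStack"), is(img, "PixelImage"))
  if (stack@kind != "raw") .stopf("stack is already normalized")
  counts <- values(img)
  d <- dim(stack@values)
  if (!all(dim(counts) == d[1:2])) .stopf("stack and image shapes differ")
  if (any(counts < 0)) .stopf("negative counts in image")
  nO <- d[3L]
  A <- Mod(stack@values)
  dim(A) <- c(d[1L] * d[2L], nO)
  out <- .normalizeModulus(A, as.vector(counts), nO, tol)
  dim(out) <- d
  new("OrientationStack", values = out, kind = "normalized",
      binSize = stack@binSize, origin = stack@origin, angles = stack@angles,
      so = stack@so)
}

#' One-step orientation analysis of a localization table
#'
#' Convenience wrapper: bins localizations, builds (or reuses) a filter bank
#' and returns the normalized orientation stack together with the histogram
#' image.
#'
#' @inheritParams binLocalizations
#' @inheritParams buildFilterBank
#' @param bank optional prebuilt [FilterBank-class] (reused across calls).
#' @return list with elements `image`, `stack`, `bank`.
#' @export
orientationAnalysis <- function(locs, binSize = 10, extent = NULL, so = 200,
                                nO = 41L, wq = 0.8 / so, bank = NULL,
                                warn = TRUE) {
  img <- binLocalizations(locs, binSize = binSize, extent = extent, warn = warn)
  if (is.null(bank))
    bank <- buildFilterBank(dim(values(img)), binSize = binSize, so = so,
                            nO = nO, wq = wq)
  arr <- .orientNormArr(values(img), bank)
  stack <- new("OrientationStack", values = arr, kind = "normalized",
               binSize = binSize(img), origin = gridOrigin(img),
               angles = bank@angles, so = bank@so)
  list(image = img, stack = stack, bank = bank)
}

#' Persist orientation stacks as multi-page TIFF
#'
#' Writes one 32-bit float page per orientation plus a JSON metadata sidecar
#' (`<path>.json`) recording bin size, orientation scale, orientation count,
#' origin and value kind. For raw stacks the modulus is stored.
#'
#' @param stack an [OrientationStack-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeOrientationStack <- function(stack, path) {
  stopifnot(is(stack, "OrientationStack"))
  v <- stack@values
  if (is.complex(v)) v <- Mod(v)
  mx <- max(max(v), .Machine$double.eps)
  pages <- lapply(seq_along(stack@angles), function(k) v[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(binSize = stack@binSize, so = stack@so,
               nO = length(stack@angles), origin = stack@origin,
               kind = stack@kind, scale = mx)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeOrientationStack
#' @export
readOrientationStack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1L]]), meta$nO))
  for (k in seq_len(meta$nO)) arr[, , k] <- pages[[k]] * meta$scale
  new("OrientationStack", values = arr, kind = meta$kind,
      binSize = meta$binSize, origin = meta$origin,
      angles = .orientationGrid(meta$nO), so = meta$so)
}
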