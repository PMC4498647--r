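#' Local co-orientation strength map
#'
#' Evaluates the anisotropic Ripley's K statistic in square subregions of
#' side `3R` whose centers are displaced by multiples of R horizontally and
#' vertically (adjacent subregions overlap by two thirds). Each subregion
#' uses the exact cross-correlation of its cropped orientation stacks, but
#' with the *global* mean densities over the field of view in the
#' denominator, so values are comparable across the image. Subregions are
#' anchored at the image corner and only fully interior subregions are
#' evaluated; the full-resolution map is obtained by bilinear interpolation
#' between subregion centers, with the border strip taking the nearest
#' center's value.
#'
#' @param stack1,stack2 normalized [OrientationStack-class] objects on the
#'   same grid.
#' @param R disc radius in nm; the image must be at least `3R` on each side.
#' @param weight angular weight, as in [kParallel()]. With `"cos2phi"`,
#'   filament crossings score negatively; with `"cossq"` the map also
#'   responds to mere co-localization and crossings do not cancel.
#' @return a [LocalKMap-class].
#' @export
localKMap <- function(stack1, stack2, R, weight = "cos2phi") {
  stopifnot(is(stack1, "OrientationStack"), is(stack2, "OrientationStack"))
  d <- dim(stack1@values)
  if (!all(dim(stack2@values) == d)) .stopf("stacks have mismatched grids")
  a <- stack1@binSize
  Rpx <- as.integer(round(R / a))
  side <- 3L * Rpx
  if (d[1L] < side || d[2L] < side)
    .stopf("image (%d x %d px) is smaller than 3R = %d px", d[1L], d[2L], side)
  nO <- d[3L]
  dphiBin <- pi / nO
  I1 <- dphiBin * rowSums(stack1@values, dims = 2L)
  I2 <- dphiBin * rowSums(stack2@values, dims = 2L)
  means <- c(mean(I1), mean(I2))
  if (any(means <= 0)) .stopf("empty channel")
  nCy <- (d[1L] - side) %/% Rpx + 1L
  nCx <- (d[2L] - side) %/% Rpx + 1L
  starts <- function(n) 1L + (seq_len(n) - 1L) * Rpx
  sy <- starts(nCy); sx <- starts(nCx)
  kmat <- matrix(NA_real_, nCy, nCx)
  for (ii in seq_len(nCy)) {
    for (jj in seq_len(nCx)) {
      ry <- sy[ii]:(sy[ii] + side - 1L)
      rx <- sx[jj]:(sx[jj] + side - 1L)
      s1 <- new("OrientationStack", values = stack1@values[ry, rx, , drop = FALSE],
                kind = "normalized", binSize = a, origin = stack1@origin,
                angles = stack1@angles, so = stack1@so)
      s2 <- new("OrientationStack", values = stack2@values[ry, rx, , drop = FALSE],
                kind = "normalized", binSize = a, origin = stack2@origin,
                angles = stack2@angles, so = stack2@so)
      cm <- crossCorrelate(s1, s2, roi = NULL, lagMax = R, means = means)
      kmat[ii, jj] <- kValue(kParallel(cm, R, weight))
    }
  }
  centerY <- sy + (side - 1) / 2
  centerX <- sx + (side - 1) / 2
  full <- .bilinearExpand(kmat, centerY, centerX, d[1L], d[2L])
  new("LocalKMap", values = kmat, centerX = centerX, centerY = centerY,
      full = full, R = R, weight = if (is.function(weight)) "custom" else weight,
      means = means)
}

# Bilinear interpolation of a coarse grid (values at given pixel-coordinate
# centers) onto the full pixel grid; outside the center hull, clamp to the
# nearest center (border strip).
.bilinearExpand <- function(kmat, centerY, centerX, ny, nx) {
  yq <- pmin(pmax(seq_len(ny), centerY[1L]), centerY[length(centerY)])
  xq <- pmin(pmax(seq_len(nx), centerX[1L]), centerX[length(centerX)])
  iy <- findInterval(yq, centerY, rightmost.closed = TRUE)
  ix <- findInterval(xq, centerX, rightmost.closed = TRUE)
  iy <- pmin(iy, length(centerY) - 1L); iy <- pmax(iy, 1L)
  ix <- pmin(ix, length(centerX) - 1L); ix <- pmax(ix, 1L)
  if (length(centerY) == 1L) { iy <- rep(1L, ny); ty <- rep(0, ny) } else
    ty <- (yq - centerY[iy]) / (centerY[iy + 1L] - centerY[iy])
  if (length(centerX) == 1L) { ix <- rep(1L, nx); tx <- rep(0, nx) } else
    tx <- (xq - centerX[ix]) / (centerX[ix + 1L] - centerX[ix])
  iy2 <- if (length(centerY) == 1L) iy else iy + 1L
  ix2 <- if (length(centerX) == 1L) ix else ix + 1L
  TY <- matrix(ty, ny, nx); TX <- matrix(tx, ny, nx, byrow = TRUE)
  k11 <- kmat[iy, ix, drop = FALSE]
  k21 <- kmat[iy2, ix, drop = FALSE]
  k12 <- kmat[iy, ix2, drop = FALSE]
  k22 <- kmat[iy2, ix2, drop = FALSE]
  (1 - TY) * (1 - TX) * k11 + TY * (1 - TX) * k21 +
    (1 - TY) * TX * k12 + TY * TX * k22
}

# Circular binary kernel of radius rPx centered at the origin pixel,
# embedded in a (py, px) fft-ordered array.
.discKernelFft <- function(rPx, py, px) {
  r <- as.integer(ceiling(rPx))
  lags <- (-r):r
  disc <- outer(lags^2, lags^2, `+`) <= rPx^2 + 1e-9
  out <- matrix(0, py, px)
  out[.lagIndex(lags, py), .lagIndex(lags, px)] <- disc + 0
  out
}

#' Fast convolutional approximation of the local co-orientation map
#'
#' Approximates [localKMap()] with convolutions: channel 1's orientation
#' stack is convolved with the kernel `g(x, phi) = cos(2*phi) * O(x/R)`
#' (disc of radius R in space, circular cosine along the orientation axis),
#' multiplied pointwise by channel 2's stack, summed over orientation, and
#' smoothed with a normalized disc kernel `O(x/3R)`. The scale constant
#' `2 * dphi^2 / (N_R * <I1> * <I2>)` (with `N_R` the number of lag pixels
#' in the disc of radius R) follows from the exact map's formula when the
#' per-lag mask overlap is replaced by a constant, so the approximate map is
#' on the same scale as the exact one; agreement is at the rank level
#' because the smoothing geometry differs from the exact subregions.
#'
#' @inheritParams localKMap
#' @return a [LocalKMap-class] (full-resolution map only; no center grid).
#' @export
fastLocalK <- function(stack1, stack2, R, weight = "cos2phi") {
  stopifnot(is(stack1, "OrientationStack"), is(stack2, "OrientationStack"))
  d <- dim(stack1@values)
  if (!all(dim(stack2@values) == d)) .stopf("stacks have mismatched grids")
  a <- stack1@binSize
  Rpx <- R / a
  if (d[1L] < 3 * Rpx || d[2L] < 3 * Rpx) .stopf("image is smaller than 3R")
  nO <- d[3L]
  dphiBin <- pi / nO
  I1 <- dphiBin * rowSums(stack1@values, dims = 2L)
  I2 <- dphiBin * rowSums(stack2@values, dims = 2L)
  means <- c(mean(I1), mean(I2))
  pad <- as.integer(ceiling(3 * Rpx)) + 1L
  py <- .goodSize(d[1L] + pad); px <- .goodSize(d[2L] + pad)
  discR <- .discKernelFft(Rpx, py, px)
  nR <- sum(discR)
  wvec <- .kWeight(weight)(.dphiGrid(nO)$dphi)
  wFft <- numeric(nO)
  wFft[.dphiGrid(nO)$perm] <- wvec
  G <- array(0, c(py, px, nO))
  for (m in seq_len(nO)) G[, , m] <- discR * wFft[m]
  conv <- Re(fft(fft(.padSpatial(stack1@values, py, px)) * fft(G),
                 inverse = TRUE)) / (py * px * nO)
  conv <- conv[seq_len(d[1L]), seq_len(d[2L]), , drop = FALSE]
  P <- rowSums(stack2@values * conv, dims = 2L)
  # disc smoothing, normalized to a mean
  disc3 <- .discKernelFft(3 * Rpx, py, px)
  Pp <- .padSpatial(P, py, px)
  Ws <- matrix(0, py, px); Ws[seq_len(d[1L]), seq_len(d[2L])] <- 1
  Fd <- fft(disc3)
  sm <- Re(fft(fft(Pp) * Fd, inverse = TRUE)) / (py * px)
  cnt <- Re(fft(fft(Ws) * Fd, inverse = TRUE)) / (py * px)
  smooth <- (sm / pmax(cnt, 1))[seq_len(d[1L]), seq_len(d[2L])]
  konst <- 2 * dphiBin^2 / (nR * means[1L] * means[2L])
  full <- konst * smooth
  new("LocalKMap", values = matrix(numeric(0), 0, 0), centerX = numeric(0),
      centerY = numeric(0), full = full, R = R,
      weight = if (is.function(weight)) "custom" else weight, means = means)
}

# Clip-and-stretch used for overlay channels: negatives to 0, brightest
# clipFraction of pixels clipped, linear scale to [0, 1].
.stretch <- function(x, clipFraction) {
  x <- pmax(x, 0)
  hi <- if (clipFraction > 0) quantile(x, 1 - clipFraction, names = FALSE)
        else max(x)
  if (hi <= 0) return(x * 0)
  pmin(x / hi, 1)
}

#' Render a local co-orientation overlay
#'
#' Composes an RGB image with the two data channels in red and green and the
#' local co-orientation strength map in blue. The map's negative values are
#' set to 0, its brightest `clipFraction` of pixels are clipped and the rest
#' scaled linearly to full range; the data channels get the same treatment
#' with `channelClip`.
#'
#' @param img1,img2 [PixelImage-class] renderings of the two channels (same
#'   grid as the map).
#' @param map a [LocalKMap-class] with a full-resolution map.
#' @param clipFraction fraction of brightest map pixels clipped (default 0.03).
#' @param channelClip clip fraction for the data channels (default 0.02).
#' @param path optional PNG output path.
#' @return numeric array (rows, cols, 3) in `[0, 1]`, invisibly if written.
#' @export
renderOverlay <- function(img1, img2, map, clipFraction = 0.03,
                          channelClip = 0.02, path = NULL) {
  stopifnot(is(map, "LocalKMap"))
  full <- map@full
  d <- dim(full)
  if (!all(dim(values(img1)) == d) || !all(dim(values(img2)) == d))
    .stopf("images and map must share the grid")
  rgb <- array(0, c(d, 3L))
  rgb[, , 1L] <- .stretch(values(img1), channelClip)
  rgb[, , 2L] <- .stretch(values(img2), channelClip)
  rgb[, , 3L] <- .stretch(full, clipFraction)
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}

#' Export a local K map as 32-bit float TIFF
#'
#' @param map a [LocalKMap-class].
#' @param path output path.
#' @export
writeLocalKMap <- function(map, path) {
  stopifnot(is(map, "LocalKMap"))
  v <- map@full
  lo <- min(v); hi <- max(v)
  tiff::writeTIFF((v - lo) / max(hi - lo, .Machine$double.eps), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(R = map@R, weight = map@weight, min = lo, max = hi),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
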