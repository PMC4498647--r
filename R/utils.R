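#' @importFrom stats fft rnorm runif rpois rgeom pnorm quantile sd
#' @importFrom utils head tail
NULL

# FFT grid sizes with only small prime factors; stats::fft degrades sharply
# on sizes with large prime factors.
.goodSize <- function(n) {
  if (n <= 1L) return(1L)
  best <- Inf
  p2 <- 1L
  while (p2 < 4L * n) {
    p23 <- p2
    while (p23 < 4L * n) {
      p235 <- p23
      while (p235 < 4L * n) {
        if (p235 >= n && p235 < best) best <- p235
        p235 <- p235 * 5L
      }
      p23 <- p23 * 3L
    }
    p2 <- p2 * 2L
  }
  as.integer(best)
}

# DFT sample frequencies (cycles per unit length), standard fft ordering.
.fftfreq <- function(n, d = 1) {
  k <- 0:(n - 1L)
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k / (n * d)
}

# Wrap angles to (-pi, pi].
.wrapAngle <- function(a) {
  w <- a %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

# Wrap orientation differences to (-pi/2, pi/2] (orientations are pi-periodic).
.wrapOrientation <- function(a) {
  w <- a %% pi
  w[w > pi / 2] <- w[w > pi / 2] - pi
  w
}

.fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Index of spatial lag d (in pixels, possibly negative) in fft output of length n.
.lagIndex <- function(d, n) ifelse(d >= 0L, d + 1L, n + d + 1L)

# Orientation bin centers phi_k = -pi/2 + k*pi/nO, k = 0..nO-1; spans [-pi/2, pi/2).
.orientationGrid <- function(nO) -pi / 2 + (0:(nO - 1L)) * pi / nO

# Signed orientation-difference values for circular lag m = 0..nO-1,
# reordered to ascending order; returns list(dphi, perm) where perm maps
# ascending positions to fft lag indices.
.dphiGrid <- function(nO) {
  m <- 0:(nO - 1L)
  ms <- m
  ms[ms > nO %/% 2] <- ms[ms > nO %/% 2] - nO
  dphi <- ms * pi / nO
  ord <- order(dphi)
  list(dphi = dphi[ord], perm = ord)
}

# Embed a 2D matrix or 3D array into a zero array of the given spatial size,
# anchored at [1,1].
.padSpatial <- function(x, py, px) {
  d <- dim(x)
  if (length(d) == 2L) {
    out <- matrix(0, py, px)
    out[seq_len(d[1L]), seq_len(d[2L])] <- x
  } else {
    out <- array(0, c(py, px, d[3L]))
    out[seq_len(d[1L]), seq_len(d[2L]), ] <- x
  }
  out
}

# Histogram raw coordinate vectors on a fixed grid (fast internal binning).
.binCounts <- function(x, y, extent, binSize, ny, nx) {
  ix <- floor((x - extent[1L]) / binSize) + 1
  iy <- floor((y - extent[3L]) / binSize) + 1
  keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  matrix(tabulate((ix[keep] - 1) * ny + iy[keep], nbins = nx * ny), ny, nx)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
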