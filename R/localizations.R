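#' Construct a LocalizationSet
#'
#' @param x,y coordinates in nm.
#' @param sigma per-localization precision in nm (> 0).
#' @param photons signal photon counts (>= 1).
#' @param frame camera frame indices.
#' @param channel channel label.
#' @param fluorophore optional fluorophore id (simulation ground truth).
#' @param extras optional data.frame of extra columns carried along.
#' @return a [LocalizationSet-class].
#' @examples
#' locs <- LocalizationSet(x = c(5, 15), y = c(5, 5), sigma = c(10, 10),
#'                         photons = c(1000, 1200), frame = c(1, 2))
#' nLocalizations(locs)
#' @export
LocalizationSet <- function(x, y, sigma, photons, frame,
                            channel = "ch", fluorophore = NULL, extras = NULL) {
  records <- data.frame(x = as.numeric(x), y = as.numeric(y),
                        sigma = as.numeric(sigma),
                        photons = as.numeric(photons),
                        frame = as.integer(frame))
  if (!is.null(fluorophore)) records$fluorophore <- as.integer(fluorophore)
  if (!is.null(extras)) records <- cbind(records, extras)
  new("LocalizationSet", records = records, channel = as.character(channel))
}

.csvColumnMap <- c(x = "x_nm", y = "y_nm", sigma = "sigma_nm",
                   photons = "photons", frame = "frame")

#' Read / write localization tables as CSV
#'
#' The on-disk dialect has a header row with columns `frame`, `x_nm`, `y_nm`,
#' `sigma_nm`, `photons` and optionally `background`; comma separated,
#' `.` decimal, UTF-8. Column order is free and unknown columns are preserved
#' round-trip as extra columns.
#'
#' @param path file path.
#' @param channel channel label to attach on read.
#' @return `readLocalizations` returns a [LocalizationSet-class];
#'   `writeLocalizations` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' locs <- LocalizationSet(1:3, 4:6, c(5, 5, 5), c(900, 900, 900), 1:3)
#' writeLocalizations(locs, f)
#' identical(localizations(readLocalizations(f)), localizations(locs))
#' @export
readLocalizations <- function(path, channel = "ch") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  dt <- data.table::fread(path, sep = ",", dec = ".", encoding = "UTF-8",
                          data.table = FALSE)
  miss <- setdiff(unname(.csvColumnMap), names(dt))
  miss <- setdiff(miss, "background")
  if (length(miss))
    .stopf("missing mandatory column(s): %s", paste(miss, collapse = ", "))
  bad <- which(!is.finite(dt$x_nm) | !is.finite(dt$y_nm))
  if (length(bad))
    .stopf("malformed row(s) at line(s): %s",
           paste(head(bad + 1L, 5L), collapse = ", "))
  extraNames <- setdiff(names(dt), unname(.csvColumnMap))
  LocalizationSet(dt$x_nm, dt$y_nm, dt$sigma_nm, dt$photons, dt$frame,
                  channel = channel,
                  extras = if (length(extraNames)) dt[extraNames] else NULL)
}

#' @rdname readLocalizations
#' @param locs a [LocalizationSet-class].
#' @export
writeLocalizations <- function(locs, path) {
  stopifnot(is(locs, "LocalizationSet"))
  r <- localizations(locs)
  out <- data.frame(frame = r$frame, x_nm = r$x, y_nm = r$y,
                    sigma_nm = r$sigma, photons = r$photons)
  extraNames <- setdiff(names(r), c("x", "y", "sigma", "photons", "frame"))
  for (nm in extraNames) out[[nm]] <- r[[nm]]
  data.table::fwrite(out, path, sep = ",", dec = ".")
  invisible(path)
}

#' Bin localizations into a 2D histogram image
#'
#' Converts a localization table into a pixel image by counting localizations
#' in square bins: a point at position p falls in bin `floor((p - origin) /
#' binSize)` (half-open bins). Localizations outside the extent are dropped
#' and counted in the result's `nDropped` slot. A warning is issued when the
#' bin size exceeds 1.5 times the median localization precision, the regime
#' in which pixelation starts to discard localization information.
#'
#' @param locs a [LocalizationSet-class].
#' @param binSize bin size in nm (default 10).
#' @param extent numeric `c(xmin, xmax, ymin, ymax)` in nm (half-open
#'   intervals); default spans the data.
#' @param warn set `FALSE` to suppress the pixel-size guard (used internally
#'   in rotation loops).
#' @return a [PixelImage-class] of integer counts.
#' @examples
#' locs <- LocalizationSet(c(5, 15), c(5, 5), c(10, 10), c(1e3, 1e3), 1:2)
#' values(binLocalizations(locs, 10, extent = c(0, 20, 0, 10)))
#' @export
binLocalizations <- function(locs, binSize = 10, extent = NULL, warn = TRUE) {
  stopifnot(is(locs, "LocalizationSet"))
  if (binSize <= 0) .stopf("binSize must be > 0")
  r <- localizations(locs)
  bad <- which(!is.finite(r$x) | !is.finite(r$y))
  if (length(bad))
    .stopf("non-finite coordinates in record(s) %s",
           paste(head(bad, 5L), collapse = ", "))
  if (is.null(extent)) {
    if (!nrow(r)) .stopf("empty extent: no data and no extent given")
    extent <- c(min(r$x), max(r$x) + binSize, min(r$y), max(r$y) + binSize)
  }
  if (extent[2L] <= extent[1L] || extent[4L] <= extent[3L])
    .stopf("empty extent")
  nx <- as.integer(ceiling((extent[2L] - extent[1L]) / binSize - 1e-9))
  ny <- as.integer(ceiling((extent[4L] - extent[3L]) / binSize - 1e-9))
  img <- matrix(0, ny, nx)
  dropped <- 0L
  if (nrow(r)) {
    if (warn && nrow(r) > 1L) {
      medSigma <- median(r$sigma)
      if (is.finite(medSigma) && binSize > 1.5 * medSigma)
        .warnf("bin size %.3g nm exceeds 1.5 x median precision (%.3g nm); pixelation may discard localization information",
               binSize, medSigma)
    }
    ix <- floor((r$x - extent[1L]) / binSize) + 1
    iy <- floor((r$y - extent[3L]) / binSize) + 1
    keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    dropped <- sum(!keep)
    if (any(keep))
      img <- matrix(tabulate((ix[keep] - 1) * ny + iy[keep], nbins = nx * ny),
                    ny, nx)
  }
  new("PixelImage", values = img, binSize = binSize,
      origin = c(extent[1L], extent[3L]), nDropped = as.integer(dropped))
}

#' Group localizations from the same blink event
#'
#' Merges chains of localizations in consecutive frames that are spatially
#' nearby - closer than three times the sum of the localizations' precisions -
#' into single localization events. Chains grow transitively: a localization
#' in frame f+1 joins a chain if it is within threshold of the chain's running
#' inverse-variance-weighted mean position. Merged records get the weighted
#' mean position (weights 1/sigma^2), the implied combined precision
#' `(sum 1/sigma^2)^(-1/2)`, the summed photon count and the chain's first
#' frame. The merge pass is repeated until no further merges occur, so the
#' operation is idempotent.
#'
#' @param locs a [LocalizationSet-class] with frames present.
#' @return a grouped [LocalizationSet-class].
#' @examples
#' locs <- LocalizationSet(c(0, 10), c(0, 0), c(5, 5), c(500, 700), c(5, 6))
#' nLocalizations(groupLocalizations(locs))  # merged into one event
#' @export
groupLocalizations <- function(locs) {
  stopifnot(is(locs, "LocalizationSet"))
  repeat {
    grouped <- .groupOnce(locs)
    if (nLocalizations(grouped) == nLocalizations(locs)) return(grouped)
    locs <- grouped
  }
}

.groupOnce <- function(locs) {
  r <- localizations(locs)
  if (nrow(r) < 2L) return(locs)
  ord <- order(r$frame)
  r <- r[ord, , drop = FALSE]
  n <- nrow(r)
  # chain state: weighted sums and bookkeeping
  cw <- cx <- cy <- cph <- numeric(n)   # sum w, sum w*x, sum w*y, photons
  cf0 <- clast <- integer(n)            # first frame, last frame
  nChains <- 0L
  assign <- integer(n)
  frames <- r$frame
  for (i in seq_len(n)) {
    f <- frames[i]
    w <- 1 / r$sigma[i]^2
    active <- which(clast[seq_len(nChains)] == f - 1L)
    joined <- FALSE
    if (length(active)) {
      mx <- cx[active] / cw[active]
      my <- cy[active] / cw[active]
      dist <- sqrt((mx - r$x[i])^2 + (my - r$y[i])^2)
      thr <- 3 * (1 / sqrt(cw[active]) + r$sigma[i])
      ok <- which(dist < thr)
      if (length(ok)) {
        j <- active[ok[which.min(dist[ok])]]
        cw[j] <- cw[j] + w
        cx[j] <- cx[j] + w * r$x[i]
        cy[j] <- cy[j] + w * r$y[i]
        cph[j] <- cph[j] + r$photons[i]
        clast[j] <- f
        assign[i] <- j
        joined <- TRUE
      }
    }
    if (!joined) {
      nChains <- nChains + 1L
      cw[nChains] <- w
      cx[nChains] <- w * r$x[i]
      cy[nChains] <- w * r$y[i]
      cph[nChains] <- r$photons[i]
      cf0[nChains] <- f
      clast[nChains] <- f
      assign[i] <- nChains
    }
  }
  k <- seq_len(nChains)
  LocalizationSet(x = cx[k] / cw[k], y = cy[k] / cw[k],
                  sigma = 1 / sqrt(cw[k]), photons = cph[k], frame = cf0[k],
                  channel = channelName(locs))
}
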