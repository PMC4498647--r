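#' Accessors
#'
#' Small accessor generics used across the package's classes.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("orientationAngles", function(x) standardGeneric("orientationAngles"))
#' @rdname accessors
#' @export
setGeneric("nOrientations", function(x) standardGeneric("nOrientations"))
#' @rdname accessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))
#' @rdname accessors
#' @export
setGeneric("localizations", function(x) standardGeneric("localizations"))
#' @rdname accessors
#' @export
setGeneric("nLocalizations", function(x) standardGeneric("nLocalizations"))
#' @rdname accessors
#' @export
setGeneric("kValue", function(x) standardGeneric("kValue"))
#' @rdname accessors
#' @export
setGeneric("pValueOf", function(x) standardGeneric("pValueOf"))
#' @rdname accessors
#' @export
setGeneric("sigma2Of", function(x) standardGeneric("sigma2Of"))

#' @rdname accessors
#' @export
setMethod("values", "PixelImage", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("values", "OrientationStack", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("values", "CoorientationMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("values", "LocalKMap", function(x) x@full)

#' @rdname accessors
#' @export
setMethod("binSize", "PixelImage", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "OrientationStack", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("binSize", "FilterBank", function(x) x@binSize)

#' @rdname accessors
#' @export
setMethod("gridOrigin", "PixelImage", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("gridOrigin", "OrientationStack", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("orientationAngles", "FilterBank", function(x) x@angles)
#' @rdname accessors
#' @export
setMethod("orientationAngles", "OrientationStack", function(x) x@angles)
#' @rdname accessors
#' @export
setMethod("nOrientations", "FilterBank", function(x) x@nO)
#' @rdname accessors
#' @export
setMethod("nOrientations", "OrientationStack", function(x) length(x@angles))

#' @rdname accessors
#' @export
setMethod("channelName", "LocalizationSet", function(x) x@channel)
#' @rdname accessors
#' @export
setMethod("localizations", "LocalizationSet", function(x) x@records)
#' @rdname accessors
#' @export
setMethod("nLocalizations", "LocalizationSet", function(x) nrow(x@records))

#' @rdname accessors
#' @export
setMethod("kValue", "KResult", function(x) x@K)
#' @rdname accessors
#' @export
setMethod("kValue", "NullProfile", function(x) x@K[1L])
#' @rdname accessors
#' @export
setMethod("pValueOf", "NullProfile", function(x) x@p)
#' @rdname accessors
#' @export
setMethod("sigma2Of", "NullProfile", function(x) x@sigma2)

setMethod("show", "LocalizationSet", function(object) {
  cat(sprintf("LocalizationSet '%s': %d localizations\n",
              object@channel, nrow(object@records)))
  if (nrow(object@records)) {
    r <- object@records
    cat(sprintf("  x: [%.1f, %.1f] nm  y: [%.1f, %.1f] nm  median sigma: %.2f nm\n",
                min(r$x), max(r$x), min(r$y), max(r$y), median(r$sigma)))
  }
})

setMethod("show", "PixelImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("PixelImage %d x %d, bin %.3g nm, origin (%.4g, %.4g) nm, sum %.6g\n",
              d[1L], d[2L], object@binSize, object@origin[1L], object@origin[2L],
              sum(object@values)))
  if (object@nDropped > 0L)
    cat(sprintf("  %d localizations outside extent were dropped\n", object@nDropped))
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf(paste0("FilterBank: s_o = %.4g nm, n_o = %d, w_phi = %.4g rad, ",
                     "w_q = %.4g 1/nm\n  padded grid %d x %d (pad %d px, bin %.3g nm)\n"),
              object@so, object@nO, object@wPhi, object@wq,
              object@paddedDim[1L], object@paddedDim[2L], object@padPx,
              object@binSize))
})

setMethod("show", "OrientationStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("OrientationStack (%s): %d x %d x %d, s_o = %.4g nm, bin %.3g nm\n",
              object@kind, d[1L], d[2L], d[3L], object@so, object@binSize))
})

setMethod("show", "CoorientationMap", function(object) {
  d <- dim(object@values)
  cat(sprintf(paste0("CoorientationMap: lags %d x %d (step %.3g nm), %d orientation",
                     " differences\n  channel means %.4g / %.4g per pixel over %d ROI pixels\n"),
              d[1L], d[2L], object@lagStep, d[3L], object@means[1L],
              object@means[2L], as.integer(object@maskSum)))
})

setMethod("show", "KResult", function(object) {
  cat(sprintf("K(R = %.4g nm, %s) = %.6g  [%d lag pixels]\n",
              object@R, object@weight, object@K, object@nPixels))
})

setMethod("show", "NullProfile", function(object) {
  cat(sprintf("NullProfile: K(R = %.4g nm) = %.6g over %d rotations\n",
              object@R, object@K[1L], length(object@theta)))
  if (length(object@sigma2))
    cat(sprintf("  sigma_K = %.6g, one-sided p = %.4g\n",
                sqrt(object@sigma2), object@p))
})

setMethod("show", "LocalKMap", function(object) {
  cat(sprintf("LocalKMap (R = %.4g nm, %s): %d x %d centers, full map %d x %d\n",
              object@R, object@weight, length(object@centerY), length(object@centerX),
              nrow(object@full), ncol(object@full)))
})

setMethod("show", "FilamentSet", function(object) {
  cat(sprintf("FilamentSet: %d filaments, segment %.3g nm, xi = %.4g nm\n",
              length(object@vertices), object@segLen, object@xi))
})

setMethod("show", "AffineMap2D", function(object) {
  cat("AffineMap2D:\n  linear part:\n")
  print(object@A)
  cat(sprintf("  shift: (%.4g, %.4g) nm, in-sample RMS %.4g nm", object@shift[1L],
              object@shift[2L], object@rms))
  if (!is.null(object@tre)) cat(sprintf(", leave-one-out TRE %.4g nm", object@tre))
  cat(sprintf("  [%d pairs]\n", object@nPoints))
})

#' @importFrom stats median
NULL
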