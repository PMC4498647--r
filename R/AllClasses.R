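#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' LocalizationSet: a single-channel SMLM localization table
#'
#' Coordinate-based representation of single-molecule localization microscopy
#' data: one record per localization with position (nm), localization
#' precision (nm), photon count and camera frame index. An optional
#' fluorophore id column carries simulation ground truth.
#'
#' @slot records data.frame with columns `x`, `y`, `sigma`, `photons`,
#'   `frame` and optionally `fluorophore` plus arbitrary extra columns.
#' @slot channel character scalar channel label.
#' @export
setClass("LocalizationSet",
  representation(records = "data.frame", channel = "character"))

setValidity("LocalizationSet", function(object) {
  r <- object@records
  need <- c("x", "y", "sigma", "photons", "frame")
  miss <- setdiff(need, names(r))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(r)) {
    bad <- which(!is.finite(r$x) | !is.finite(r$y))
    if (length(bad)) return(paste("non-finite coordinates in record(s)",
                                  paste(head(bad, 5L), collapse = ", ")))
    if (any(r$sigma <= 0, na.rm = TRUE)) return("precision sigma must be > 0")
    if (any(r$photons < 1, na.rm = TRUE)) return("photon counts must be >= 1")
  }
  TRUE
})

#' PixelImage: localizations binned on a square grid
#'
#' A 2D histogram (or continuous density) of localizations, with the bin size
#' in nm and the physical origin of the grid. Pixel `[i, j]` covers the
#' half-open square `[origin + (j-1, i-1)*binSize, origin + (j, i)*binSize)`
#' with rows indexing y (increasing downward) and columns indexing x.
#'
#' @slot values numeric matrix of non-negative values.
#' @slot binSize bin size in nm.
#' @slot origin physical (x, y) position in nm of the grid corner.
#' @slot nDropped number of localizations outside the extent (histograms).
#' @export
setClass("PixelImage",
  representation(values = "matrix", binSize = "numeric",
                 origin = "numeric", nDropped = "integer"),
  prototype(binSize = 10, origin = c(0, 0), nDropped = 0L))

setValidity("PixelImage", function(object) {
  if (object@binSize <= 0) return("binSize must be > 0")
  if (length(object@origin) != 2L) return("origin must be length 2")
  if (any(object@values < 0)) return("pixel values must be non-negative")
  TRUE
})

#' FilterBank: Fourier-domain orientation-selective filters
#'
#' A stack of scale- and orientation-selective band-pass filters sampled on
#' the FFT frequency grid of a zero-padded image. Each filter peaks (with
#' modulus 2) on the frequency ring q = 1/s_o at its nominal orientation and
#' is zero at DC. The angular response uses a single lobe in the full
#' frequency circle so spatial-domain kernels are complex.
#'
#' @slot so orientation scale in nm (radial pass band centered at 1/so).
#' @slot wq radial bandwidth in 1/nm (default 0.8/so).
#' @slot nO number of orientation channels.
#' @slot wPhi angular bandwidth, exactly pi/nO.
#' @slot binSize pixel pitch (nm) of the image grid the bank applies to.
#' @slot imageDim image (rows, cols) before padding.
#' @slot padPx zero-padding in pixels on each side.
#' @slot paddedDim padded FFT grid (rows, cols).
#' @slot angles orientation grid phi_k in radians, in [-pi/2, pi/2).
#' @slot filters real array (paddedDim, nO) of Fourier-domain filter values.
#' @export
setClass("FilterBank",
  representation(so = "numeric", wq = "numeric", nO = "integer",
                 wPhi = "numeric", binSize = "numeric", imageDim = "integer",
                 padPx = "integer", paddedDim = "integer", angles = "numeric",
                 filters = "array"))

setValidity("FilterBank", function(object) {
  if (object@so <= 0) return("so must be > 0")
  if (object@nO < 2L) return("nO must be >= 2")
  if (abs(object@wPhi - pi / object@nO) > 1e-12) return("wPhi must equal pi/nO")
  TRUE
})

#' OrientationStack: per-orientation filtered images
#'
#' A 3D grid over (y, x, phi) holding either the raw complex orientation-space
#' response of an image to a [FilterBank] or its normalized, real-valued form
#' interpretable as the expected density of localizations per unit angle at
#' each position and orientation. Orientations are pi-periodic and the phi
#' axis is treated as circular (period pi) downstream.
#'
#' @slot values complex (raw) or double (normalized) array (rows, cols, nO).
#' @slot kind `"raw"` or `"normalized"`.
#' @slot binSize pixel pitch in nm.
#' @slot origin grid origin in nm.
#' @slot angles orientation grid in radians.
#' @slot so orientation scale (nm) of the generating filter bank.
#' @export
setClass("OrientationStack",
  representation(values = "array", kind = "character", binSize = "numeric",
                 origin = "numeric", angles = "numeric", so = "numeric"))

setValidity("OrientationStack", function(object) {
  if (!object@kind %in% c("raw", "normalized")) return("kind must be raw or normalized")
  if (length(dim(object@values)) != 3L) return("values must be a 3D array")
  if (dim(object@values)[3L] != length(object@angles)) return("third dim must match angles")
  if (object@kind == "normalized" && is.complex(object@values))
    return("normalized stacks are real")
  TRUE
})

#' Regions of interest
#'
#' `CircleROI` is a circular region (center and radius, nm); `MaskROI` is an
#' explicit binary mask aligned to a pixel grid. Circular ROIs are required by
#' the rotation-based significance test because rotation about their center
#' leaves the channel sums unchanged.
#'
#' @slot center circle center (x, y) in nm.
#' @slot radius circle radius in nm.
#' @export
setClass("RegionOfInterest", representation("VIRTUAL"))

#' @rdname RegionOfInterest-class
#' @export
setClass("CircleROI", contains = "RegionOfInterest",
  representation(center = "numeric", radius = "numeric"))

setValidity("CircleROI", function(object) {
  if (length(object@center) != 2L) return("center must be length 2")
  if (object@radius <= 0) return("radius must be > 0")
  TRUE
})

#' @rdname RegionOfInterest-class
#' @slot mask binary matrix aligned to the image grid.
#' @export
setClass("MaskROI", contains = "RegionOfInterest",
  representation(mask = "matrix"))

setValidity("MaskROI", function(object) {
  if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
  if (sum(object@mask) == 0) return("mask must be non-empty")
  TRUE
})

#' CoorientationMap: generalized cross-correlation c(dx, dy, dphi)
#'
#' The generalized cross-correlation between two normalized orientation
#' stacks as a function of spatial lag and orientation difference, normalized
#' so that statistically independent channels give c = 1. Lags with
#' insufficient mask overlap are NA and flagged invalid.
#'
#' @slot values array (2*nLag+1, 2*nLag+1, nO) of c values (NA where invalid).
#' @slot valid logical matrix of spatial-lag validity.
#' @slot dphi ascending orientation-difference grid (radians, period pi).
#' @slot lagStep spatial lag spacing (nm) = pixel pitch.
#' @slot means channel mean counts per pixel over the ROI, c(mean1, mean2).
#' @slot maskSum number of ROI pixels.
#' @export
setClass("CoorientationMap",
  representation(values = "array", valid = "matrix", dphi = "numeric",
                 lagStep = "numeric", means = "numeric", maskSum = "numeric"))

#' KResult: anisotropic Ripley's K statistic
#'
#' @slot K the K value (dimensionless).
#' @slot R disc radius in nm.
#' @slot weight angular weight used: `"cos2phi"` or `"cossq"`.
#' @slot nPixels number of valid lag pixels summed.
#' @export
setClass("KResult",
  representation(K = "numeric", R = "numeric", weight = "character",
                 nPixels = "integer"))

#' NullProfile: rotation-null profile of the K statistic
#'
#' K evaluated for channel-2 rotations over equally spaced angles theta in
#' [0, 2*pi), with the resulting null variance estimate and one-sided p-value
#' for the unrotated statistic.
#'
#' @slot theta rotation angles (radians).
#' @slot K K value per rotation; `K[1]` is the unrotated statistic.
#' @slot R disc radius (nm).
#' @slot weight angular weight.
#' @slot sigma2 estimated null variance of K.
#' @slot p one-sided upper-tail p-value.
#' @export
setClass("NullProfile",
  representation(theta = "numeric", K = "numeric", R = "numeric",
                 weight = "character", sigma2 = "numeric", p = "numeric"))

setValidity("NullProfile", function(object) {
  if (length(object@theta) < 8L) return("need at least 8 rotation angles")
  if (length(object@theta) != length(object@K)) return("theta/K length mismatch")
  if (length(object@sigma2) && object@sigma2 < 0) return("sigma2 must be >= 0")
  if (length(object@p) && (object@p < 0 || object@p > 1)) return("p must be in [0,1]")
  TRUE
})

#' LocalKMap: local co-orientation strength map
#'
#' K evaluated in square subregions of side 3R whose centers are spaced R
#' apart (adjacent subregions overlap by two thirds), with the global channel
#' mean densities used in every denominator, plus a full-resolution
#' bilinearly interpolated map.
#'
#' @slot values matrix of K at subregion centers (empty for the fast map).
#' @slot centerX,centerY subregion center pixel coordinates (1-based).
#' @slot full full-resolution interpolated map.
#' @slot R disc radius (nm).
#' @slot weight angular weight.
#' @slot means global channel means used in the denominators.
#' @export
setClass("LocalKMap",
  representation(values = "matrix", centerX = "numeric", centerY = "numeric",
                 full = "matrix", R = "numeric", weight = "character",
                 means = "numeric"))

#' FilamentSet: simulated filament polylines
#'
#' Wormlike-chain filaments as ordered vertex lists with fixed segment
#' length; consecutive vertices are exactly one segment length apart.
#'
#' @slot vertices list of n x 2 matrices of (x, y) in nm.
#' @slot segLen segment length in nm.
#' @slot xi persistence length in nm.
#' @export
setClass("FilamentSet",
  representation(vertices = "list", segLen = "numeric", xi = "numeric"))

#' AffineMap2D: two-channel registration map
#'
#' @slot A 2x2 linear part.
#' @slot shift translation (nm).
#' @slot rms in-sample RMS residual (nm).
#' @slot tre leave-one-recording-out target registration error (nm), or NULL.
#' @slot nPoints number of point pairs used.
#' @export
setClass("AffineMap2D",
  representation(A = "matrix", shift = "numeric", rms = "numeric",
                 tre = "numericOrNULL", nPoints = "integer"))

setValidity("AffineMap2D", function(object) {
  if (!all(dim(object@A) == c(2L, 2L))) return("A must be 2x2")
  if (abs(det(object@A)) < 1e-12) return("linear part must be invertible")
  TRUE
})

#' SimulationConfig: study conditions for the two-channel filament simulator
#'
#' Defaults are the conditions used throughout the package's validation
#' simulations: a 4 um field, wormlike chains of 10^4 segments of 1 nm,
#' antibody-linker jitter of 5 nm FWHM, blink counts min(Poisson(25),
#' Geometric(11)), geometric photon counts with mean 2000, background 1
#' photon/pixel, PSF width 1.38 camera pixels (2% spread) and a 100 nm
#' camera pixel.
#'
#' @slot fov field of view (nm).
#' @slot nFilaments number of filaments in channel 1.
#' @slot xi channel-1 persistence length (nm).
#' @slot mode channel-2 derivation: `"parallel"`, `"independent"`, `"twisted"`.
#' @slot d parallel-mode perpendicular offset (nm).
#' @slot xi2 independent-mode persistence length (nm).
#' @slot dmax,period twisted-mode maximum offset and contour period (nm).
#' @slot nFluorophores expected fluorophore count per channel.
#' @slot jitterFwhm antibody jitter FWHM (nm).
#' @slot meanBlinkPoisson,meanBlinkGeometric blink-count distribution means.
#' @slot meanPhotons mean signal photons per localization.
#' @slot meanBackground mean background photons per pixel.
#' @slot psfWidthPx,psfWidthRelSd PSF width mean (camera pixels) and relative SD.
#' @slot cameraPixel camera pixel size (nm).
#' @slot segLen,nSegments filament segment length (nm) and count.
#' @slot densityBin,densityBlurFwhm filament density rendering bin and blur (nm).
#' @slot nFrames number of camera frames available for blink trains.
#' @export
setClass("SimulationConfig",
  representation(fov = "numeric", nFilaments = "integer", xi = "numeric",
                 mode = "character", d = "numeric", xi2 = "numeric",
                 dmax = "numeric", period = "numeric",
                 nFluorophores = "numeric", jitterFwhm = "numeric",
                 meanBlinkPoisson = "numeric", meanBlinkGeometric = "numeric",
                 meanPhotons = "numeric", meanBackground = "numeric",
                 psfWidthPx = "numeric", psfWidthRelSd = "numeric",
                 cameraPixel = "numeric", segLen = "numeric",
                 nSegments = "integer", densityBin = "numeric",
                 densityBlurFwhm = "numeric", nFrames = "integer"))

setValidity("SimulationConfig", function(object) {
  pos <- c(fov = object@fov, xi = object@xi, jitterFwhm = object@jitterFwhm,
           meanBlinkPoisson = object@meanBlinkPoisson,
           meanBlinkGeometric = object@meanBlinkGeometric,
           meanPhotons = object@meanPhotons, psfWidthPx = object@psfWidthPx,
           cameraPixel = object@cameraPixel, segLen = object@segLen,
           densityBin = object@densityBin)
  if (any(pos <= 0)) return(paste("non-positive parameter:",
                                  paste(names(pos)[pos <= 0], collapse = ", ")))
  if (!object@mode %in% c("parallel", "independent", "twisted"))
    return("mode must be parallel, independent or twisted")
  if (object@mode == "parallel" && object@d <= 0) return("parallel mode needs d > 0")
  if (object@mode == "independent" && object@xi2 <= 0) return("independent mode needs xi2 > 0")
  if (object@mode == "twisted" && (object@dmax <= 0 || object@period <= 0))
    return("twisted mode needs dmax > 0 and period > 0")
  TRUE
})
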