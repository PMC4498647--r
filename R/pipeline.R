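.pipelineSchema <- c(
  "preset", "seed", "channel1", "channel2", "binSize", "so", "nO", "lagMax",
  "R", "nTheta", "weight", "roi", "extent", "localMap", "clipFraction",
  "outDir", "fov", "nFilaments", "nFluorophores", "xi", "xi2", "d", "dmax",
  "period", "group")

#' Run the full co-orientation analysis pipeline
#'
#' Orchestrates simulation (or CSV input), binning, orientation analysis,
#' cross-correlation, the rotation-null significance test and (optionally)
#' the local co-orientation map, writing a JSON report plus figures and CSV
#' dumps to an output directory. The configuration is a named list or a YAML
#' file with keys mirroring the analysis settings; unknown keys are
#' rejected by name.
#'
#' Config keys: either `preset` (+ simulator overrides `fov`, `nFilaments`,
#' `nFluorophores`, `xi`, `xi2`, `d`, `dmax`, `period`) or `channel1` /
#' `channel2` CSV paths; `binSize` (nm, default 10), `so` (nm, default 200),
#' `nO` (default 41), `lagMax` (nm, default 500), `R` (nm, default 200),
#' `nTheta` (default 49), `weight`, `roi` (`c(cx, cy, radius)` in nm;
#' default the inscribed circle), `extent`, `group` (logical: group
#' localizations first), `localMap` (logical), `clipFraction`, `seed`,
#' `outDir`.
#'
#' @param config named list or path to a YAML file.
#' @return the report, invisibly (a named list, also written as JSON when
#'   `outDir` is set).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) .stopf("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), .pipelineSchema)
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  getOr <- function(key, default) if (is.null(config[[key]])) default
                                  else config[[key]]
  seed <- getOr("seed", NULL)
  if (!is.null(seed)) set.seed(seed)
  binSizeNm <- getOr("binSize", 10)
  so <- getOr("so", 200)
  nO <- getOr("nO", 41L)
  lagMax <- getOr("lagMax", 500)
  R <- getOr("R", 200)
  nTheta <- getOr("nTheta", 49L)
  weight <- getOr("weight", "cos2phi")
  outDir <- getOr("outDir", NULL)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  message("[input] acquiring localizations")
  if (!is.null(config$preset)) {
    overrides <- config[intersect(names(config),
                                  c("fov", "nFilaments", "nFluorophores",
                                    "xi", "xi2", "d", "dmax", "period"))]
    sim <- do.call(simulateDataset,
                   c(list(preset = config$preset), overrides))
    locs1 <- sim$locs1; locs2 <- sim$locs2
    extent <- c(0, sim$config@fov, 0, sim$config@fov)
  } else {
    if (is.null(config$channel1) || is.null(config$channel2))
      .stopf("config needs either 'preset' or 'channel1' and 'channel2'")
    locs1 <- readLocalizations(config$channel1, channel = "ch1")
    locs2 <- readLocalizations(config$channel2, channel = "ch2")
    r1 <- localizations(locs1); r2 <- localizations(locs2)
    extent <- c(min(r1$x, r2$x), max(r1$x, r2$x) + binSizeNm,
                min(r1$y, r2$y), max(r1$y, r2$y) + binSizeNm)
  }
  extent <- getOr("extent", extent)
  if (isTRUE(config$group)) {
    message("[group] merging blink events")
    locs1 <- groupLocalizations(locs1)
    locs2 <- groupLocalizations(locs2)
  }
  roiSpec <- getOr("roi", c(mean(extent[1:2]), mean(extent[3:4]),
                            min(diff(extent[1:2]), diff(extent[3:4])) / 2))
  roi <- circleROI(roiSpec[1:2], roiSpec[3L])

  message("[orient] orientation-space analysis")
  oa1 <- orientationAnalysis(locs1, binSizeNm, extent, so, nO, warn = FALSE)
  oa2 <- orientationAnalysis(locs2, binSizeNm, extent, so, nO,
                             bank = oa1$bank, warn = FALSE)
  message("[coorient] generalized cross-correlation")
  map <- crossCorrelate(oa1$stack, oa2$stack, roi = roi, lagMax = lagMax)
  prof <- radialProfile(map)
  message("[ktest] rotation-null significance test")
  test <- significanceTest(locs1, locs2, roi, extent, R = R, nTheta = nTheta,
                           binSize = binSizeNm, so = so, nO = nO,
                           weight = weight, warn = FALSE)
  localK <- NULL
  if (isTRUE(config$localMap)) {
    message("[localmap] local co-orientation map")
    localK <- localKMap(oa1$stack, oa2$stack, R = R, weight = weight)
  }
  report <- list(
    settings = list(binSize = binSizeNm, so = so, nO = nO, lagMax = lagMax,
                    R = R, nTheta = nTheta, weight = weight,
                    roi = as.numeric(roiSpec), extent = as.numeric(extent),
                    seed = seed),
    nLocalizations = c(ch1 = nLocalizations(locs1),
                       ch2 = nLocalizations(locs2)),
    K = kValue(test), sigmaK = sqrt(sigma2Of(test)), p = pValueOf(test),
    significant01 = pValueOf(test) < 0.01,
    rotationK = as.numeric(test@K),
    version = as.character(utils::packageVersion("coorient")))
  if (!is.null(outDir)) {
    report$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    exportCoorientationPlot(map, png = file.path(outDir, "coorientation.png"),
                            csv = file.path(outDir, "coorientation.csv"),
                            rMax = lagMax)
    grDevices::png(file.path(outDir, "rotation_profile.png"), 720, 560)
    plotRotationProfile(test)
    grDevices::dev.off()
    if (!is.null(localK)) {
      img1 <- binLocalizations(locs1, binSizeNm, extent, warn = FALSE)
      img2 <- binLocalizations(locs2, binSizeNm, extent, warn = FALSE)
      renderOverlay(img1, img2, localK,
                    clipFraction = getOr("clipFraction", 0.03),
                    path = file.path(outDir, "overlay.png"))
      writeLocalKMap(localK, file.path(outDir, "local_k.tif"))
    }
  }
  message(sprintf("[done] K = %.4g, sigma_K = %.4g, p = %.4g",
                  report$K, report$sigmaK, report$p))
  invisible(report)
}
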