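# The end-to-end measurement of one image (or one region of interest):
# segmentation -> skeletonization -> topology (+ optional pruning) -> traits.

# Fixed column order of a feature record. Per-bin columns
# (<Trait>.Range.<i>) are appended after these.
.featureColumns <- c(
  "file_name", "roi_name", "mode",
  "tip_count", "branch_point_count",
  "branching_frequency_per_px", "branching_frequency_per_mm",
  "total_length_px", "total_length_mm",
  "network_area_px2", "network_area_mm2",
  "avg_diameter_px", "avg_diameter_mm",
  "median_diameter_px", "median_diameter_mm",
  "max_diameter_px", "max_diameter_mm",
  "perimeter_px", "perimeter_mm",
  "surface_area_px2", "surface_area_mm2",
  "volume_px3", "volume_mm3",
  "median_roots", "max_roots",
  "depth_px", "depth_mm", "max_width_px", "max_width_mm", "width_to_depth",
  "convex_area_px2", "convex_area_mm2", "solidity",
  "lower_root_area_px2", "lower_root_area_mm2",
  "hole_count", "avg_hole_size_px2", "avg_hole_size_mm2",
  "steep_angle_freq", "medium_angle_freq", "shallow_angle_freq",
  "avg_root_orientation_deg",
  "computation_time_s")

.emptyRecord <- function(fileName, roiName, mode, nBins) {
  rec <- as.data.frame(as.list(stats::setNames(rep(0, length(.featureColumns)),
                                               .featureColumns)),
                       stringsAsFactors = FALSE)
  rec$file_name <- fileName
  rec$roi_name <- roiName
  rec$mode <- mode
  for (tr in c("Length", "ProjectedArea", "SurfaceArea", "Volume"))
    for (i in seq_len(nBins)) rec[[sprintf("%s.Range.%d", tr, i)]] <- 0
  rec
}

#' Crop an image to a region of interest
#'
#' ROI coordinates are 0-based with the origin at the image's top-left and y
#' growing downward. Rectangles are clipped to the image bounds with a
#' warning; an ROI entirely outside the image yields `NULL`.
#'
#' @param img a [RootImage-class].
#' @param roi a one-row data.frame with `x`, `y`, `width`, `height`.
#' @return The cropped [RootImage-class], or `NULL`.
#' @export
cropImage <- function(img, roi) {
  p <- pixels(img)
  r1 <- roi$y + 1L; c1 <- roi$x + 1L
  r2 <- roi$y + roi$height; c2 <- roi$x + roi$width
  if (r1 > nrow(p) || c1 > ncol(p) || r2 < 1L || c2 < 1L) {
    warning("ROI '", roi$name, "' lies entirely outside the image")
    return(NULL)
  }
  if (r1 < 1L || c1 < 1L || r2 > nrow(p) || c2 > ncol(p)) {
    warning("ROI '", roi$name, "' clipped to the image bounds")
    r1 <- max(r1, 1L); c1 <- max(c1, 1L)
    r2 <- min(r2, nrow(p)); c2 <- min(c2, ncol(p))
  }
  rootImage(p[r1:r2, c1:c2, drop = FALSE], pxPerMm = pxPerMm(img))
}

#' Segment an image according to analysis options
#'
#' Applies, in order: global thresholding, background component-size
#' filtering, hole filling and contour smoothing (each optional step only
#' when enabled in `config`). Sizes are taken in mm^2 when a resolution is
#' known, else px^2.
#'
#' @param img a [RootImage-class].
#' @param config an [AnalysisConfig-class].
#' @return A [RootMask-class].
#' @export
segmentImage <- function(img, config) {
  s <- configPxPerMm(config, img)
  img2 <- rootImage(pixels(img), pxPerMm = s)
  mask <- thresholdImage(img2, config@thresholdLevel, config@invert)
  units <- if (length(s)) "mm2" else "px2"
  if (config@filterBackground)
    mask <- filterBackgroundNoise(mask, config@maxComponentSize, units)
  if (config@fillHoles)
    mask <- fillHoles(mask, config@maxHoleSize, units)
  if (config@edgeSmoothing)
    mask <- smoothContours(mask, config@rdpTolerancePx)
  mask
}

#' Extract the full trait record from one image
#'
#' Runs segmentation, skeletonization, topology (with pruning, alternated
#' with false-loop suppression, when enabled) and all mode-appropriate
#' traits on the image or on one region of interest. Shared traits are identical between the two modes; branch
#' statistics are reported only in broken-roots mode and the crown traits
#' only in whole-root mode (inapplicable fields are `NA`). An empty
#' segmentation yields a record of zeros with a warning so batch runs
#' complete.
#'
#' @param img a [RootImage-class].
#' @param config an [AnalysisConfig-class].
#' @param roi optional one-row ROI data.frame (see [readROIFile()]).
#' @param fileName,roiName identifiers carried into the record.
#' @return A one-row data.frame (the feature record) in the fixed column
#'   order, with per-bin columns `<Trait>.Range.<i>` for length, projected
#'   area, surface area and volume.
#' @examples
#' scene <- renderWires(list(wireSpec(1, 20, position = c(20, 10))),
#'                      pxPerMm = 10)
#' cfg <- analysisConfig(thresholdLevel = 191, pxPerMm = 10)
#' rec <- extractFeatures(scene$image, cfg)
#' rec$total_length_mm
#' @export
extractFeatures <- function(img, config, roi = NULL, fileName = "",
                            roiName = "") {
  stopifnot(is(img, "RootImage"), is(config, "AnalysisConfig"))
  t0 <- proc.time()[["elapsed"]]
  nBins <- length(config@diameterBinEdges) + 1L
  mode <- config@mode
  if (!is.null(roi)) {
    if (!nzchar(roiName)) roiName <- as.character(roi$name)
    img <- cropImage(img, roi)
    if (is.null(img)) {
      rec <- .emptyRecord(fileName, roiName, mode, nBins)
      rec$computation_time_s <- proc.time()[["elapsed"]] - t0
      return(rec)
    }
  }
  mask <- segmentImage(img, config)
  s <- pxPerMm(mask)
  if (!any(pixels(mask))) {
    warning("empty segmentation for ", fileName, ": record of zeros")
    rec <- .emptyRecord(fileName, roiName, mode, nBins)
    rec$computation_time_s <- proc.time()[["elapsed"]] - t0
    return(rec)
  }
  skel <- buildSkeleton(mask)
  topo <- classifyPixels(skel)
  if (config@pruningEnabled) {
    pruned <- .refineSkeleton(skel, topo, mask, config@pruningThresholdPx)
    skel <- pruned$skeleton
    topo <- pruned$topology
  }

  len <- totalLength(skel)
  dia <- diameterStats(skel)
  area <- networkArea(mask)
  per <- rootPerimeter(mask)
  sav <- surfaceAreaVolume(skel)
  binUnits <- if (length(s)) "mm" else "px"
  bins <- binnedHistograms(skel, config@diameterBinEdges, units = binUnits)

  rec <- .emptyRecord(fileName, roiName, mode, nBins)
  rec$tip_count <- countTips(topo)
  rec$total_length_px <- len[["px"]]; rec$total_length_mm <- len[["mm"]]
  rec$network_area_px2 <- area[["px2"]]; rec$network_area_mm2 <- area[["mm2"]]
  rec$avg_diameter_px <- dia[["avg_px"]]
  rec$avg_diameter_mm <- dia[["avg_mm"]]
  rec$median_diameter_px <- dia[["median_px"]]
  rec$median_diameter_mm <- dia[["median_mm"]]
  rec$max_diameter_px <- dia[["max_px"]]
  rec$max_diameter_mm <- dia[["max_mm"]]
  rec$perimeter_px <- per[["px"]]; rec$perimeter_mm <- per[["mm"]]
  rec$surface_area_px2 <- sav[["surface_area_px2"]]
  rec$surface_area_mm2 <- sav[["surface_area_mm2"]]
  rec$volume_px3 <- sav[["volume_px3"]]
  rec$volume_mm3 <- sav[["volume_mm3"]]

  if (mode == "broken_roots") {
    rec$branch_point_count <- countBranchPoints(topo)
    bf <- branchingFrequency(topo, len)
    rec$branching_frequency_per_px <- bf[["per_px"]]
    rec$branching_frequency_per_mm <- bf[["per_mm"]]
    for (col in c("median_roots", "max_roots", "depth_px", "depth_mm",
                  "max_width_px", "max_width_mm", "width_to_depth",
                  "convex_area_px2", "convex_area_mm2", "solidity",
                  "lower_root_area_px2", "lower_root_area_mm2", "hole_count",
                  "avg_hole_size_px2", "avg_hole_size_mm2",
                  "steep_angle_freq", "medium_angle_freq",
                  "shallow_angle_freq", "avg_root_orientation_deg"))
      rec[[col]] <- NA_real_
  } else {
    rec$branch_point_count <- NA_real_
    rec$branching_frequency_per_px <- NA_real_
    rec$branching_frequency_per_mm <- NA_real_
    rc <- rowRootCounts(mask)
    rec$median_roots <- rc[["median"]]; rec$max_roots <- rc[["max"]]
    ext <- extentMetrics(mask)
    rec$depth_px <- ext[["depth_px"]]; rec$depth_mm <- ext[["depth_mm"]]
    rec$max_width_px <- ext[["max_width_px"]]
    rec$max_width_mm <- ext[["max_width_mm"]]
    rec$width_to_depth <- ext[["width_to_depth"]]
    cm <- convexMetrics(mask, area[["px2"]])
    rec$convex_area_px2 <- cm[["convex_area_px2"]]
    rec$convex_area_mm2 <- cm[["convex_area_mm2"]]
    rec$solidity <- cm[["solidity"]]
    lra <- lowerRootArea(mask, skel)
    rec$lower_root_area_px2 <- lra[["px2"]]
    rec$lower_root_area_mm2 <- lra[["mm2"]]
    hm <- holeMetrics(mask)
    rec$hole_count <- hm[["hole_count"]]
    rec$avg_hole_size_px2 <- hm[["avg_size_px2"]]
    rec$avg_hole_size_mm2 <- hm[["avg_size_mm2"]]
    af <- angleFeatures(skel)
    rec$steep_angle_freq <- af[["steep_freq"]]
    rec$medium_angle_freq <- af[["medium_freq"]]
    rec$shallow_angle_freq <- af[["shallow_freq"]]
    rec$avg_root_orientation_deg <- af[["avg_orientation_deg"]]
  }
  for (i in seq_len(nBins)) {
    rec[[sprintf("Length.Range.%d", i)]] <- bins$length[i]
    rec[[sprintf("ProjectedArea.Range.%d", i)]] <- bins$projected_area[i]
    rec[[sprintf("SurfaceArea.Range.%d", i)]] <- bins$surface_area[i]
    rec[[sprintf("Volume.Range.%d", i)]] <- bins$volume[i]
  }
  rec$computation_time_s <- proc.time()[["elapsed"]] - t0
  rec
}
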