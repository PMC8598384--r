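# Batch analysis: single-image and directory runs, feature/settings CSV
# output, ground-truth benchmarking and the diagnostic feature image.

.imageExts <- c("png", "jpg", "jpeg", "bmp", "tif", "tiff")

# Sidecar ROI annotation file convention: <image path without extension>.roi
.roiSidecar <- function(imagePath)
  paste0(tools::file_path_sans_ext(imagePath), ".roi")

#' Analyse one image
#'
#' Produces one feature record per region of interest, or a single record
#' for the whole image when no ROI file is given. ROIs partly outside the
#' image are clipped with a warning; an ROI entirely outside it yields a
#' record of zeros.
#'
#' @param imagePath path of the image.
#' @param config an [AnalysisConfig-class].
#' @param roiPath optional ROI annotation file ([readROIFile()]).
#' @return A data.frame of feature records (one row per ROI or one row
#'   total).
#' @export
runSingle <- function(imagePath, config, roiPath = NULL) {
  img <- loadImage(imagePath)
  fileName <- basename(imagePath)
  if (is.null(roiPath))
    return(extractFeatures(img, config, fileName = fileName))
  rois <- readROIFile(roiPath)
  if (!nrow(rois))
    return(extractFeatures(img, config, fileName = fileName))
  do.call(rbind, lapply(seq_len(nrow(rois)), function(i)
    extractFeatures(img, config, roi = rois[i, ], fileName = fileName)))
}

#' Analyse every image in a directory
#'
#' Applies the same settings to all supported images (PNG, JPEG, BMP, TIFF)
#' in `dirPath`, in deterministic lexicographic order. A sidecar annotation
#' file `<image>.roi` is honoured per image when present. Per-file failures
#' are logged and the batch continues. Writes `features.csv` (one row per
#' image/ROI) and `metadata.csv` (every settings value used) to `outDir`.
#'
#' @param dirPath directory of images.
#' @param config an [AnalysisConfig-class].
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list with `features` (data.frame), `failures`
#'   (character vector of failed files) and the two output paths.
#' @export
runBatch <- function(dirPath, config, outDir = dirPath) {
  if (!dir.exists(dirPath)) stop("no such directory: ", dirPath)
  files <- list.files(dirPath, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% .imageExts]
  files <- files[order(basename(files), method = "radix")]
  if (!length(files)) stop("no supported images in ", dirPath)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  records <- list()
  failures <- character(0)
  for (f in files) {
    roi <- .roiSidecar(f)
    rec <- tryCatch(
      runSingle(f, config, roiPath = if (file.exists(roi)) roi else NULL),
      error = function(e) {
        message("failed on ", basename(f), ": ", conditionMessage(e))
        NULL
      })
    if (is.null(rec)) failures <- c(failures, basename(f))
    else records[[length(records) + 1L]] <- rec
  }
  if (!length(records)) stop("every image in the batch failed")
  features <- do.call(rbind, records)
  featPath <- file.path(outDir, "features.csv")
  metaPath <- file.path(outDir, "metadata.csv")
  writeFeatureCSV(features, featPath)
  writeConfig(config, metaPath)
  invisible(list(features = features, failures = failures,
                 features_csv = featPath, metadata_csv = metaPath))
}

#' Write feature records to CSV
#'
#' One header row and one data row per image/ROI, in the fixed column order
#' of [extractFeatures()].
#'
#' @param features data.frame of feature records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Benchmark a directory of images against ground truth
#'
#' Batch-analyses the directory, joins the estimates to the truth table by
#' file name and reports RMSE, MBE and R^2 per trait (unmatched files are
#' excluded with a warning). The truth CSV must be keyed by `file_name` with
#' trait columns named as in the feature records (e.g. `total_length_mm`,
#' `avg_diameter_mm`, `surface_area_mm2`, `volume_mm3`).
#'
#' @param imageDir directory of images.
#' @param truthCsv path of the ground-truth CSV.
#' @param config an [AnalysisConfig-class].
#' @param traits optional restriction of the traits compared.
#' @param reportCsv optional path to also write the report to.
#' @return A data.frame: `trait`, `n`, `rmse`, `mbe`, `r_squared`.
#' @export
runBenchmark <- function(imageDir, truthCsv, config, traits = NULL,
                         reportCsv = NULL) {
  truth <- utils::read.csv(truthCsv, stringsAsFactors = FALSE)
  if (!"file_name" %in% names(truth))
    stop("truth CSV must have a file_name column")
  est <- runBatch(imageDir, config, outDir = tempfile("rqbench"))$features
  report <- benchmarkReport(est, truth, traits = traits)
  if (!is.null(reportCsv)) utils::write.csv(report, reportCsv,
                                            row.names = FALSE)
  report
}

#' Export a mask, distance map or skeleton as a debug PNG
#'
#' Binary masks are written black-on-white; numeric matrices (e.g. a
#' distance map) are scaled to full range; skeletons are written as their
#' radius map. Purely diagnostic.
#'
#' @param x a [RootMask-class], [RadiusSkeleton-class] or numeric matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeDebugPNG <- function(x, path) {
  m <- if (is(x, "RootMask")) 1 - pixels(x)
  else if (is(x, "RadiusSkeleton")) {
    r <- radiusMap(x)
    if (max(r) > 0) 1 - r / max(r) else r + 1
  } else if (is.matrix(x)) {
    if (max(x) > 0) 1 - x / max(x) else x + 1
  } else stop("cannot export object of class ", class(x)[1])
  png::writePNG(m, path)
  invisible(path)
}

#' Render a diagnostic feature image
#'
#' Overlay raster of the analysis: the segmented root in grey, the skeleton
#' coloured by diameter bin, optional tip (green) and branch-point (blue)
#' markers and, in whole-root mode, the convex hull outline. Purely
#' informational; has no effect on any measurement.
#'
#' @param mask a [RootMask-class].
#' @param skel the matching [RadiusSkeleton-class].
#' @param topo optional [RootTopology-class] for tip/branch markers.
#' @param binEdges diameter bin edges (px) colouring the skeleton.
#' @param mode `"broken_roots"` or `"whole_root"` (draws the hull).
#' @param file optional PNG path to write.
#' @return The height x width x 3 RGB array, invisibly.
#' @export
renderFeatureImage <- function(mask, skel, topo = NULL,
                               binEdges = numeric(),
                               mode = "broken_roots", file = NULL) {
  m <- pixels(mask)
  nr <- nrow(m); nc <- ncol(m)
  rgb <- array(1, dim = c(nr, nc, 3))
  for (k in 1:3) {
    ch <- rgb[, , k]
    ch[m] <- 0.8
    rgb[, , k] <- ch
  }
  paint <- function(sel, col) {
    for (k in 1:3) {
      ch <- rgb[, , k]
      ch[sel] <- col[k]
      rgb[, , k] <<- ch
    }
  }
  s <- skeletonPixels(skel)
  if (any(s)) {
    nBins <- length(binEdges) + 1L
    pal <- grDevices::col2rgb(grDevices::hcl.colors(max(nBins, 2L),
                                                    "Zissou 1")) / 255
    d <- 2 * radiusMap(skel)
    bin <- findInterval(d, binEdges, left.open = TRUE) + 1L
    for (b in seq_len(nBins)) paint(s & bin == b, pal[, b])
  }
  if (!is.null(topo)) {
    paint(topologyLabels(topo) == TIP, c(0, 0.8, 0))
    paint(topologyLabels(topo) == BRANCH, c(0, 0, 1))
  }
  if (mode == "whole_root" && any(m)) {
    idx <- which(m)
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    hull <- grDevices::chull(cc, rr)
    ol <- .polyOutline(cbind(rr[hull], cc[hull]))
    sel <- matrix(FALSE, nr, nc)
    sel[ol] <- TRUE
    paint(sel, c(1, 0.5, 0))
  }
  if (!is.null(file)) png::writePNG(rgb, file)
  invisible(rgb)
}
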