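#' @import methods
NULL

# ---------------------------------------------------------------------------
# Classes
# ---------------------------------------------------------------------------

#' Greyscale root scan
#'
#' A 2-D intensity raster with optional spatial-resolution metadata. Pixel
#' values are 8-bit intensities (0--255) regardless of the source bit depth;
#' 16-bit scans are reduced by integer division by 257 and colour scans keep
#' only their red channel. Row 1 is the top of the image and depth grows with
#' the row index.
#'
#' @slot pixels numeric matrix of intensities in `[0, 255]`.
#' @slot pxPerMm numeric of length 0 (pixel-only mode) or 1 (pixels per mm).
#' @seealso [loadImage()], [thresholdImage()]
#' @export
setClass("RootImage",
  representation(pixels = "matrix", pxPerMm = "numeric"))

setValidity("RootImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1x1")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("intensities must lie in [0, 255]")
  if (length(object@pxPerMm) > 1L)
    return("pxPerMm must have length 0 or 1")
  if (length(object@pxPerMm) == 1L &&
      (!is.finite(object@pxPerMm) || object@pxPerMm <= 0))
    return("pxPerMm must be positive")
  TRUE
})

#' Binary root mask
#'
#' Segmentation of root pixels (TRUE = root) with the source image's shape
#' and resolution metadata carried through.
#'
#' @slot pixels logical matrix, TRUE on root pixels.
#' @slot pxPerMm numeric of length 0 or 1.
#' @seealso [thresholdImage()], [filterBackgroundNoise()], [fillHoles()],
#'   [smoothContours()]
#' @export
setClass("RootMask",
  representation(pixels = "matrix", pxPerMm = "numeric"))

setValidity("RootMask", function(object) {
  p <- object@pixels
  if (!is.logical(p)) return("mask pixels must be a logical matrix")
  if (anyNA(p)) return("mask pixels must not contain NA")
  if (length(object@pxPerMm) > 1L) return("pxPerMm must have length 0 or 1")
  if (length(object@pxPerMm) == 1L &&
      (!is.finite(object@pxPerMm) || object@pxPerMm <= 0))
    return("pxPerMm must be positive")
  TRUE
})

#' Radius-annotated medial axis
#'
#' One-pixel-wide, 8-connected skeleton of a [RootMask-class]. The `radius`
#' matrix holds, at every skeleton pixel, the Euclidean distance-transform
#' value there (the local root radius in px) and 0 elsewhere, mirroring how
#' the skeletal image stores distance-map values for diameter work downstream.
#'
#' @slot radius numeric matrix; positive exactly on skeleton pixels.
#' @slot pxPerMm numeric of length 0 or 1.
#' @seealso [buildSkeleton()], [classifyPixels()]
#' @export
setClass("RadiusSkeleton",
  representation(radius = "matrix", pxPerMm = "numeric"))

setValidity("RadiusSkeleton", function(object) {
  r <- object@radius
  if (!is.numeric(r)) return("radius must be a numeric matrix")
  if (anyNA(r) || min(r) < 0) return("radii must be non-negative")
  if (length(object@pxPerMm) > 1L) return("pxPerMm must have length 0 or 1")
  TRUE
})

# Integer codes for topological pixel classes.
TIP <- 1L
BRANCH <- 2L
SEGMENT <- 3L

#' Skeleton topology
#'
#' Per-skeletal-pixel class labels plus the segment decomposition. Codes in
#' the `labels` matrix: 0 = not skeleton, 1 = tip (at most one skeleton
#' neighbour), 2 = branch point (three or more neighbours), 3 = interior
#' segment pixel (exactly two neighbours). Each element of `segments` is a
#' list with `path` (n x 2 matrix of row/col pixels between two endpoints,
#' endpoints included), `length_px` (sum of unit/diagonal steps) and
#' `end_types` (two of `"TIP"`/`"BRANCH"`, or `"LOOP"` for pure cycles).
#'
#' @slot labels integer matrix of class codes.
#' @slot segments list of segment records.
#' @seealso [classifyPixels()], [pruneSkeleton()]
#' @export
setClass("RootTopology",
  representation(labels = "matrix", segments = "list"))

#' Analysis options
#'
#' Bundles every tunable of the measurement pipeline. Component and hole
#' sizes and diameter bin edges are interpreted in mm-based units when a
#' resolution is known and in pixel units otherwise.
#'
#' @slot mode `"broken_roots"` (washed root fragments, the default) or
#'   `"whole_root"` (connected root crowns; adds extent, convex-hull, hole
#'   and angle traits).
#' @slot thresholdLevel global threshold in `[0, 255]`; a pixel is root when
#'   its intensity is `<=` the level (roots darker than the background)
#'   unless `invert` is set.
#' @slot invert logical; segment pixels brighter than the level instead.
#' @slot filterBackground,maxComponentSize logical flag and maximum area of a
#'   noisy root component to erase (mm^2 when a resolution is set, else px^2).
#' @slot fillHoles,maxHoleSize logical flag and maximum area of an enclosed
#'   background hole to fill.
#' @slot edgeSmoothing,rdpTolerancePx logical flag and Ramer-Douglas-Peucker
#'   pixel tolerance for contour simplification.
#' @slot pruningEnabled,pruningThresholdPx logical flag and the extra pixel
#'   margin added to the branch-point radius when pruning short laterals.
#' @slot diameterBinEdges strictly ascending diameter bin edges.
#' @slot dpi,pxPerMm optional resolution (each length 0 or 1; at most one
#'   may be set).
#' @seealso [analysisConfig()], [readConfig()], [extractFeatures()]
#' @export
setClass("AnalysisConfig",
  representation(
    mode = "character",
    thresholdLevel = "numeric",
    invert = "logical",
    filterBackground = "logical",
    maxComponentSize = "numeric",
    fillHoles = "logical",
    maxHoleSize = "numeric",
    edgeSmoothing = "logical",
    rdpTolerancePx = "numeric",
    pruningEnabled = "logical",
    pruningThresholdPx = "numeric",
    diameterBinEdges = "numeric",
    dpi = "numeric",
    pxPerMm = "numeric"))

setValidity("AnalysisConfig", function(object) {
  if (!object@mode %in% c("broken_roots", "whole_root"))
    return("mode must be 'broken_roots' or 'whole_root'")
  if (object@thresholdLevel < 0 || object@thresholdLevel > 255)
    return("thresholdLevel must be in [0, 255]")
  if (object@rdpTolerancePx < 0) return("rdpTolerancePx must be >= 0")
  if (object@pruningThresholdPx < 0)
    return("pruningThresholdPx must be >= 0")
  e <- object@diameterBinEdges
  if (length(e) && (any(e < 0) || any(diff(e) <= 0)))
    return("diameterBinEdges must be non-negative and strictly ascending")
  if (length(object@dpi) > 1L || length(object@pxPerMm) > 1L)
    return("dpi and pxPerMm must each have length 0 or 1")
  if (length(object@dpi) && length(object@pxPerMm))
    return("give at most one of dpi and pxPerMm")
  if (length(object@dpi) && object@dpi <= 0) return("dpi must be positive")
  if (length(object@pxPerMm) && object@pxPerMm <= 0)
    return("pxPerMm must be positive")
  if (object@maxComponentSize < 0 || object@maxHoleSize < 0)
    return("component/hole sizes must be >= 0")
  TRUE
})

# ---------------------------------------------------------------------------
# Constructors
# ---------------------------------------------------------------------------

#' Create a RootImage from a pixel matrix
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @param pxPerMm optional pixels-per-mm resolution (length-0 numeric means
#'   pixel-only mode).
#' @return A [RootImage-class].
#' @examples
#' img <- rootImage(matrix(255, 10, 10))
#' @export
rootImage <- function(pixels, pxPerMm = numeric()) {
  new("RootImage", pixels = pixels, pxPerMm = as.numeric(pxPerMm))
}

#' Create a RootMask from a logical matrix
#'
#' @param pixels logical matrix (TRUE = root).
#' @param pxPerMm optional pixels-per-mm resolution.
#' @return A [RootMask-class].
#' @export
rootMask <- function(pixels, pxPerMm = numeric()) {
  storage.mode(pixels) <- "logical"
  new("RootMask", pixels = pixels, pxPerMm = as.numeric(pxPerMm))
}

#' Create analysis options
#'
#' All arguments default to the documented defaults: broken-roots mode,
#' threshold 128, every optional filter off, pruning margin 5 px.
#'
#' @param mode,thresholdLevel,invert,filterBackground,maxComponentSize,fillHoles,maxHoleSize,edgeSmoothing,rdpTolerancePx,pruningEnabled,pruningThresholdPx,diameterBinEdges,dpi,pxPerMm
#'   see [AnalysisConfig-class].
#' @return An [AnalysisConfig-class].
#' @examples
#' cfg <- analysisConfig(thresholdLevel = 191, filterBackground = TRUE,
#'                       maxComponentSize = 8, pruningEnabled = TRUE,
#'                       pruningThresholdPx = 5, dpi = 600)
#' @export
analysisConfig <- function(mode = "broken_roots",
                           thresholdLevel = 128,
                           invert = FALSE,
                           filterBackground = FALSE,
                           maxComponentSize = 8,
                           fillHoles = FALSE,
                           maxHoleSize = 8,
                           edgeSmoothing = FALSE,
                           rdpTolerancePx = 2,
                           pruningEnabled = FALSE,
                           pruningThresholdPx = 5,
                           diameterBinEdges = numeric(),
                           dpi = numeric(),
                           pxPerMm = numeric()) {
  new("AnalysisConfig",
      mode = mode,
      thresholdLevel = as.numeric(thresholdLevel),
      invert = isTRUE(invert),
      filterBackground = isTRUE(filterBackground),
      maxComponentSize = as.numeric(maxComponentSize),
      fillHoles = isTRUE(fillHoles),
      maxHoleSize = as.numeric(maxHoleSize),
      edgeSmoothing = isTRUE(edgeSmoothing),
      rdpTolerancePx = as.numeric(rdpTolerancePx),
      pruningEnabled = isTRUE(pruningEnabled),
      pruningThresholdPx = as.numeric(pruningThresholdPx),
      diameterBinEdges = as.numeric(diameterBinEdges),
      dpi = as.numeric(dpi),
      pxPerMm = as.numeric(pxPerMm))
}

# ---------------------------------------------------------------------------
# Generics and accessors
# ---------------------------------------------------------------------------

#' @rdname accessors
#' @param x an object of one of the classes above.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Accessors for rootquant objects
#'
#' `pixels()` returns the intensity or mask matrix, `pxPerMm()` the
#' resolution (length-0 numeric when unknown), `radiusMap()` the per-pixel
#' radius matrix of a skeleton, `skeletonPixels()` its logical support,
#' `topologyLabels()` the integer class-code matrix and `rootSegments()` the
#' list of traced segments.
#'
#' @name accessors
#' @return See each accessor's description.
#' @aliases pixels pxPerMm radiusMap skeletonPixels topologyLabels
#'   rootSegments
NULL

#' @rdname accessors
#' @export
setMethod("pixels", "RootImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "RootMask", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("pxPerMm", function(x) standardGeneric("pxPerMm"))

#' @rdname accessors
#' @export
setMethod("pxPerMm", "RootImage", function(x) x@pxPerMm)

#' @rdname accessors
#' @export
setMethod("pxPerMm", "RootMask", function(x) x@pxPerMm)

#' @rdname accessors
#' @export
setMethod("pxPerMm", "RadiusSkeleton", function(x) x@pxPerMm)

#' @rdname accessors
#' @export
setGeneric("radiusMap", function(x) standardGeneric("radiusMap"))

#' @rdname accessors
#' @export
setMethod("radiusMap", "RadiusSkeleton", function(x) x@radius)

#' @rdname accessors
#' @export
setGeneric("skeletonPixels", function(x) standardGeneric("skeletonPixels"))

#' @rdname accessors
#' @export
setMethod("skeletonPixels", "RadiusSkeleton", function(x) x@radius > 0)

#' @rdname accessors
#' @export
setGeneric("topologyLabels", function(x) standardGeneric("topologyLabels"))

#' @rdname accessors
#' @export
setMethod("topologyLabels", "RootTopology", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("rootSegments", function(x) standardGeneric("rootSegments"))

#' @rdname accessors
#' @export
setMethod("rootSegments", "RootTopology", function(x) x@segments)

setMethod("dim", "RootImage", function(x) dim(x@pixels))
setMethod("dim", "RootMask", function(x) dim(x@pixels))
setMethod("dim", "RadiusSkeleton", function(x) dim(x@radius))

.resTag <- function(p)
  if (length(p)) sprintf("%.4g px/mm", p) else "pixel units"

setMethod("show", "RootImage", function(object) {
  cat(sprintf("RootImage: %d x %d px, intensities [%g, %g], %s\n",
              nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels),
              .resTag(object@pxPerMm)))
})

setMethod("show", "RootMask", function(object) {
  cat(sprintf("RootMask: %d x %d px, %d root px (%.2f%%), %s\n",
              nrow(object@pixels), ncol(object@pixels), sum(object@pixels),
              100 * mean(object@pixels), .resTag(object@pxPerMm)))
})

setMethod("show", "RadiusSkeleton", function(object) {
  s <- object@radius > 0
  if (any(s)) {
    cat(sprintf(
      "RadiusSkeleton: %d skeleton px on a %d x %d grid, radii [%.3g, %.3g] px, %s\n",
      sum(s), nrow(s), ncol(s), min(object@radius[s]),
      max(object@radius[s]), .resTag(object@pxPerMm)))
  } else {
    cat(sprintf("RadiusSkeleton: empty (%d x %d grid)\n", nrow(s), ncol(s)))
  }
})

setMethod("show", "RootTopology", function(object) {
  l <- object@labels
  cat(sprintf(
    "RootTopology: %d tips, %d branch points, %d segment px, %d segments\n",
    sum(l == TIP), sum(l == BRANCH), sum(l == SEGMENT),
    length(object@segments)))
})

setMethod("show", "AnalysisConfig", function(object) {
  res <- if (length(object@dpi)) sprintf("%g DPI", object@dpi)
         else if (length(object@pxPerMm)) sprintf("%g px/mm", object@pxPerMm)
         else "pixel units"
  cat(sprintf("AnalysisConfig: mode=%s threshold=%g invert=%s %s\n",
              object@mode, object@thresholdLevel, object@invert, res))
  cat(sprintf("  background filter: %s (max %g), hole fill: %s (max %g)\n",
              object@filterBackground, object@maxComponentSize,
              object@fillHoles, object@maxHoleSize))
  cat(sprintf("  edge smoothing: %s (tol %g px), pruning: %s (margin %g px)\n",
              object@edgeSmoothing, object@rdpTolerancePx,
              object@pruningEnabled, object@pruningThresholdPx))
  if (length(object@diameterBinEdges))
    cat("  diameter bin edges:",
        paste(object@diameterBinEdges, collapse = ", "), "\n")
})
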