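# Segmentation: global thresholding, connected-component noise filtering,
# hole filling and optional contour smoothing. Root and background components
# both use 8-connectivity; a single bright pixel with only seven root
# neighbours therefore leaks diagonally into the outer background and is not
# a hole.

#' Threshold a greyscale scan into a root mask
#'
#' A pixel is root when its intensity is `<=` `level` (roots darker than the
#' bright scanner background). With `invert = TRUE` the rule flips to
#' `> level`, for backlit images with bright roots.
#'
#' @param img a [RootImage-class].
#' @param level global threshold in `[0, 255]`.
#' @param invert segment bright-on-dark instead.
#' @return A [RootMask-class] of the same shape.
#' @examples
#' img <- rootImage(matrix(c(200, 100, 50, 255), 2, 2))
#' pixels(thresholdImage(img, 191))
#' @export
thresholdImage <- function(img, level, invert = FALSE) {
  stopifnot(is(img, "RootImage"))
  if (level < 0 || level > 255) stop("threshold level must be in [0, 255]")
  m <- if (invert) pixels(img) > level else pixels(img) <= level
  rootMask(m, pxPerMm = pxPerMm(img))
}

#' Remove small non-root components from the background
#'
#' Every 8-connected root component whose pixel area is `<=` the maximum
#' size is erased, removing soil particles and other debris left after root
#' washing. Sizes in mm^2 require a resolution on the mask and are converted
#' as `maxSize * pxPerMm^2`.
#'
#' @param mask a [RootMask-class].
#' @param maxSize maximum area of a component to erase; `0` keeps everything.
#' @param units `"px2"` or `"mm2"`.
#' @return The filtered [RootMask-class].
#' @export
filterBackgroundNoise <- function(mask, maxSize, units = c("px2", "mm2")) {
  stopifnot(is(mask, "RootMask"))
  maxPx <- areaToPx2(maxSize, match.arg(units), pxPerMm(mask))
  m <- pixels(mask)
  if (!any(m) || maxPx <= 0) return(mask)
  lab <- label8(m)
  sizes <- tabulate(lab[m], nbins = max(lab))
  drop <- which(sizes <= maxPx)
  if (length(drop)) m[lab %in% drop] <- FALSE
  rootMask(m, pxPerMm = pxPerMm(mask))
}

#' Fill small enclosed holes inside roots
#'
#' A hole is an 8-connected background component that does not touch the
#' image border (so it is fully surrounded by root). Holes with area `<=`
#' the maximum size become root, recovering bright spots inside roots that
#' thresholding labelled as background. A background pixel with a diagonal
#' background neighbour is connected to it and is not a hole.
#'
#' @inheritParams filterBackgroundNoise
#' @param maxSize maximum hole area to fill.
#' @return The filled [RootMask-class].
#' @export
fillHoles <- function(mask, maxSize, units = c("px2", "mm2")) {
  stopifnot(is(mask, "RootMask"))
  maxPx <- areaToPx2(maxSize, match.arg(units), pxPerMm(mask))
  m <- pixels(mask)
  if (maxPx <= 0) return(mask)
  bg <- label8(!m)
  if (max(bg) == 0) return(mask)
  holes <- setdiff(seq_len(max(bg)), borderLabels(bg))
  if (!length(holes)) return(mask)
  sizes <- tabulate(bg[!m], nbins = max(bg))
  fill <- holes[sizes[holes] <= maxPx]
  if (length(fill)) m[bg %in% fill] <- TRUE
  rootMask(m, pxPerMm = pxPerMm(mask))
}

#' Smooth mask contours with the Ramer-Douglas-Peucker simplifier
#'
#' Each component's closed outer contour and the inner contours around its
#' holes are simplified within `tolerancePx` and the mask is re-rasterized
#' from the filled simplified polygons. Smoothing removes boundary
#' roughness that would otherwise seed short invalid lateral roots during
#' skeletonization. A tolerance of 0 reproduces the input mask. Tolerances
#' above 2.0 px can alter the root topology and give contours an angular
#' appearance, so they trigger a warning.
#'
#' @param mask a [RootMask-class].
#' @param tolerancePx maximum perpendicular deviation of the simplified
#'   contour, in pixels (>= 0).
#' @return The smoothed [RootMask-class].
#' @export
smoothContours <- function(mask, tolerancePx) {
  stopifnot(is(mask, "RootMask"))
  if (tolerancePx < 0) stop("tolerancePx must be >= 0")
  if (tolerancePx > 2)
    warning("contour smoothing tolerances above 2.0 px may alter root topology")
  m <- pixels(mask)
  if (tolerancePx == 0 || !any(m)) return(mask)
  cont <- maskContours(m)
  comps <- unique(vapply(cont, `[[`, integer(1), "component"))
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (id in comps) {
    outer <- NULL
    holes <- list()
    for (ct in cont) {
      if (ct$component != id) next
      simplified <- rdpClosed(ct$path, tolerancePx)
      if (ct$type == "outer") outer <- simplified
      else holes[[length(holes) + 1L]] <- simplified
    }
    out <- out | rasterizePolyComponent(outer, holes, nrow(m), ncol(m))
  }
  rootMask(out, pxPerMm = pxPerMm(mask))
}
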