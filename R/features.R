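# Trait extraction. Shared traits are computed for both analysis modes;
# branch statistics are reported for broken-roots mode and the root-crown
# traits (extent, convex hull, holes, angles, row counts, lower root area)
# for whole-root mode. Values carry both pixel and mm variants when a
# resolution is known.
#
# Per-pixel cylinder model: every skeleton pixel p is a cylinder of radius
# r(p) (its distance-map value) and height h(p) = half the sum of Euclidean
# distances to its skeleton neighbours, so that the heights sum exactly to
# the total root length. Summing h*pi*r^2 and h*2*pi*r per pixel gives
# volume and surface area that respect diameter heterogeneity, unlike the
# length x average-diameter cylinder shortcut which is biased low whenever
# thin and thick roots share an image.

.mmOrNA <- function(px, s, power = 1)
  if (length(s) == 1L && is.finite(s)) px / s^power else NA_real_

# Half-sum of distances to skeleton neighbours, per pixel (the cylinder
# heights); zero off-skeleton and for isolated pixels.
.cylinderHeights <- function(s) {
  orth <- shiftMat(s, 0, 1, FALSE) + shiftMat(s, 0, -1, FALSE) +
    shiftMat(s, 1, 0, FALSE) + shiftMat(s, -1, 0, FALSE)
  diag <- shiftMat(s, 1, 1, FALSE) + shiftMat(s, 1, -1, FALSE) +
    shiftMat(s, -1, 1, FALSE) + shiftMat(s, -1, -1, FALSE)
  0.5 * (orth + sqrt(2) * diag) * s
}

#' Total root length
#'
#' Sum over the skeleton's 8-adjacency edges of the Euclidean step length
#' (1 for orthogonal, sqrt(2) for diagonal neighbours), each edge counted
#' once.
#'
#' @param skel a [RadiusSkeleton-class].
#' @return Named numeric `c(px = , mm = )` (`mm` is `NA` without a
#'   resolution).
#' @examples
#' m <- matrix(FALSE, 3, 11); m[2, ] <- TRUE
#' totalLength(buildSkeleton(rootMask(m)))  # 10 px
#' @export
totalLength <- function(skel) {
  s <- skeletonPixels(skel)
  nOrth <- sum(s & shiftMat(s, 0, 1, FALSE)) + sum(s & shiftMat(s, 1, 0, FALSE))
  nDiag <- sum(s & shiftMat(s, 1, 1, FALSE)) + sum(s & shiftMat(s, 1, -1, FALSE))
  px <- nOrth + sqrt(2) * nDiag
  c(px = px, mm = .mmOrNA(px, pxPerMm(skel)))
}

#' Diameter statistics
#'
#' The distance-map value at each skeletal pixel is the local radius and is
#' doubled to give the diameter; average, median and maximum are computed
#' across all skeleton pixels, unweighted by default. `weighted = TRUE`
#' weights each pixel by its cylinder height (length-weighted average).
#'
#' @param skel a [RadiusSkeleton-class].
#' @param weighted length-weight the average (median/max are unaffected).
#' @return Named numeric with `avg_px`, `median_px`, `max_px` and their `mm`
#'   counterparts; zeros (with a warning) for an empty skeleton.
#' @export
diameterStats <- function(skel, weighted = FALSE) {
  s <- skeletonPixels(skel)
  if (!any(s)) {
    warning("empty skeleton: diameters reported as 0")
    d <- c(avg = 0, median = 0, max = 0)
  } else {
    dd <- 2 * radiusMap(skel)[s]
    avg <- if (weighted) {
      w <- .cylinderHeights(s)[s]
      if (sum(w) > 0) sum(dd * w) / sum(w) else mean(dd)
    } else mean(dd)
    d <- c(avg = avg, median = stats::median(dd), max = max(dd))
  }
  sM <- pxPerMm(skel)
  c(avg_px = d[["avg"]], median_px = d[["median"]], max_px = d[["max"]],
    avg_mm = .mmOrNA(d[["avg"]], sM), median_mm = .mmOrNA(d[["median"]], sM),
    max_mm = .mmOrNA(d[["max"]], sM))
}

#' Network area
#'
#' The total number of root pixels in the segmented image (projected area of
#' the root system).
#'
#' @param mask a [RootMask-class].
#' @return Named numeric `c(px2 = , mm2 = )`.
#' @export
networkArea <- function(mask) {
  px2 <- sum(pixels(mask))
  c(px2 = px2, mm2 = .mmOrNA(px2, pxPerMm(mask), power = 2))
}

#' Perimeter of the segmented roots
#'
#' Sum of the Euclidean distances between connected contour pixels along
#' every component's closed outer contour and every inner contour around
#' enclosed holes.
#'
#' @param mask a [RootMask-class].
#' @return Named numeric `c(px = , mm = )`.
#' @export
rootPerimeter <- function(mask) {
  px <- sum(vapply(maskContours(pixels(mask)), function(ct)
    closedPathLength(ct$path), numeric(1)))
  c(px = px, mm = .mmOrNA(px, pxPerMm(mask)))
}

#' Root surface area and volume by per-pixel cylinders
#'
#' Each skeleton pixel contributes a cylinder of its local radius and of
#' height equal to half the summed distance to its skeleton neighbours
#' (heights sum to the total length). Isolated pixels contribute nothing.
#'
#' @param skel a [RadiusSkeleton-class].
#' @return Named numeric with `surface_area_px2`, `volume_px3` and mm
#'   counterparts.
#' @examples
#' m <- matrix(FALSE, 9, 15); m[3:7, 3:13] <- TRUE  # 5-px-wide bar
#' surfaceAreaVolume(buildSkeleton(rootMask(m)))
#' @export
surfaceAreaVolume <- function(skel) {
  s <- skeletonPixels(skel)
  h <- .cylinderHeights(s)
  r <- radiusMap(skel)
  sa <- sum(h * 2 * pi * r)
  vol <- sum(h * pi * r^2)
  sM <- pxPerMm(skel)
  c(surface_area_px2 = sa, volume_px3 = vol,
    surface_area_mm2 = .mmOrNA(sa, sM, 2), volume_mm3 = .mmOrNA(vol, sM, 3))
}

#' Diameter-binned length, projected area, surface area and volume
#'
#' Each skeleton pixel's cylinder contributes its height to length, height x
#' diameter to projected area (the root's footprint on the image plane),
#' height x circumference to surface area and height x cross-section to
#' volume, in the bin containing the pixel's diameter. Ranges are
#' left-open/right-closed: `(-Inf, e1], (e1, e2], ..., (ek, Inf)`. Per-bin
#' sums equal the unbinned totals exactly.
#'
#' @param skel a [RadiusSkeleton-class].
#' @param binEdges strictly ascending diameter edges, in the units requested.
#' @param units `"px"` to bin pixel diameters, `"mm"` to convert first
#'   (requires a resolution).
#' @return A data.frame with one row per bin: `bin`, `range`, `length`,
#'   `projected_area`, `surface_area`, `volume` (in the requested units).
#' @export
binnedHistograms <- function(skel, binEdges = numeric(),
                             units = c("px", "mm")) {
  units <- match.arg(units)
  if (length(binEdges) && any(diff(binEdges) <= 0))
    stop("binEdges must be strictly ascending")
  s <- skeletonPixels(skel)
  nBins <- length(binEdges) + 1L
  sM <- pxPerMm(skel)
  scale <- if (units == "mm") {
    if (length(sM) != 1L) stop("mm bins require a resolution")
    sM
  } else 1
  lo <- c(-Inf, binEdges)
  hi <- c(binEdges, Inf)
  out <- data.frame(bin = seq_len(nBins),
                    range = sprintf("(%g, %g]", lo, hi),
                    length = 0, projected_area = 0, surface_area = 0,
                    volume = 0, stringsAsFactors = FALSE)
  if (any(s)) {
    h <- .cylinderHeights(s)[s] / scale
    r <- radiusMap(skel)[s] / scale
    d <- 2 * r
    idx <- findInterval(d, binEdges, left.open = TRUE) + 1L
    sums <- function(v) {
      x <- rep(0, nBins)
      t <- rowsum(v, idx)
      x[as.integer(rownames(t))] <- t
      x
    }
    out$length <- sums(h)
    out$projected_area <- sums(h * d)
    out$surface_area <- sums(h * 2 * pi * r)
    out$volume <- sums(h * pi * r^2)
  }
  out
}

#' Branching frequency
#'
#' Branch points per unit total root length.
#'
#' @param topo a [RootTopology-class].
#' @param length named length vector from [totalLength()].
#' @return Named numeric `c(per_px = , per_mm = )`; zero with a warning when
#'   the length is zero.
#' @export
branchingFrequency <- function(topo, length) {
  n <- countBranchPoints(topo)
  if (!is.finite(length[["px"]]) || length[["px"]] <= 0) {
    if (n > 0) warning("zero root length: branching frequency reported as 0")
    return(c(per_px = 0, per_mm = 0))
  }
  perPx <- n / length[["px"]]
  perMm <- if (is.na(length[["mm"]])) NA_real_ else n / length[["mm"]]
  c(per_px = perPx, per_mm = perMm)
}

#' Median and maximum number of roots per scan line
#'
#' For every image row, counts the background-to-root pixel transitions
#' scanning left to right (a root pixel in the first column counts as a
#' transition); reports the median and maximum over rows that cross at least
#' one root.
#'
#' @param mask a [RootMask-class].
#' @return Named numeric `c(median = , max = )`; `c(0, 0)` for an empty mask.
#' @export
rowRootCounts <- function(mask) {
  m <- pixels(mask)
  if (!any(m)) return(c(median = 0, max = 0))
  starts <- m & !cbind(FALSE, m[, -ncol(m), drop = FALSE])
  counts <- rowSums(starts)
  counts <- counts[counts >= 1]
  c(median = stats::median(counts), max = max(counts))
}

#' Root crown extent
#'
#' Depth is the row extent of root pixels, maximum width the column extent
#' (both inclusive pixel counts); the ratio is width/depth.
#'
#' @param mask a [RootMask-class].
#' @return Named numeric `depth_px`, `max_width_px`, `width_to_depth` plus
#'   mm variants; zeros for an empty mask.
#' @export
extentMetrics <- function(mask) {
  m <- pixels(mask)
  sM <- pxPerMm(mask)
  if (!any(m))
    return(c(depth_px = 0, max_width_px = 0, width_to_depth = 0,
             depth_mm = .mmOrNA(0, sM), max_width_mm = .mmOrNA(0, sM)))
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  depth <- diff(rows) + 1
  width <- diff(cols) + 1
  c(depth_px = depth, max_width_px = width, width_to_depth = width / depth,
    depth_mm = .mmOrNA(depth, sM), max_width_mm = .mmOrNA(width, sM))
}

#' Convex hull area and solidity
#'
#' The convex hull is fit around all root pixel centres; its raster area is
#' the number of pixel centres inside or on the hull (hull edges are
#' included via line rasterization, so a degenerate collinear hull is the
#' digital segment through the points). Solidity is network area divided by
#' convex area.
#'
#' @param mask a [RootMask-class].
#' @param networkAreaPx2 optional precomputed root pixel count.
#' @return Named numeric `convex_area_px2`, `convex_area_mm2`, `solidity`.
#' @export
convexMetrics <- function(mask, networkAreaPx2 = NULL) {
  m <- pixels(mask)
  sM <- pxPerMm(mask)
  na <- networkAreaPx2 %||% sum(m)
  if (!any(m))
    return(c(convex_area_px2 = 0, convex_area_mm2 = .mmOrNA(0, sM, 2),
             solidity = 0))
  idx <- which(m)
  rr <- ((idx - 1L) %% nrow(m)) + 1L
  cc <- ((idx - 1L) %/% nrow(m)) + 1L
  hull <- grDevices::chull(cc, rr)     # x = col, y = row
  poly <- cbind(rr[hull], cc[hull])
  if (nrow(poly) < 3L) {
    warning("collinear root pixels: convex hull is a digital segment")
    if (nrow(poly) == 1L) poly <- rbind(poly, poly)
  }
  rmin <- min(rr); rmax <- max(rr); cmin <- min(cc); cmax <- max(cc)
  pr <- rep(rmin:rmax, times = cmax - cmin + 1L)
  pc <- rep(cmin:cmax, each = rmax - rmin + 1L)
  inHull <- if (nrow(poly) >= 3L) .pointsInPoly(pr, pc, poly)
            else logical(length(pr))
  hullMask <- matrix(FALSE, nrow(m), ncol(m))
  hullMask[cbind(pr[inHull], pc[inHull])] <- TRUE
  ol <- .polyOutline(poly)
  hullMask[ol] <- TRUE
  ca <- sum(hullMask)
  c(convex_area_px2 = ca, convex_area_mm2 = .mmOrNA(ca, sM, 2),
    solidity = na / ca)
}

#' Network area below the thickest point
#'
#' Locates the skeleton pixel with the maximum radius (ties broken by
#' smallest row, then smallest column) and counts the root pixels strictly
#' below its row.
#'
#' @param mask a [RootMask-class].
#' @param skel the matching [RadiusSkeleton-class].
#' @return Named numeric `c(px2 = , mm2 = )`; zero for an empty skeleton.
#' @export
lowerRootArea <- function(mask, skel) {
  r <- radiusMap(skel)
  sM <- pxPerMm(mask)
  if (!any(r > 0)) return(c(px2 = 0, mm2 = .mmOrNA(0, sM, 2)))
  idx <- which(r == max(r))
  rr <- ((idx - 1L) %% nrow(r)) + 1L
  cc <- ((idx - 1L) %/% nrow(r)) + 1L
  o <- order(rr, cc)[1]
  below <- sum(pixels(mask)[seq_len(nrow(r)) > rr[o], , drop = FALSE])
  c(px2 = below, mm2 = .mmOrNA(below, sM, 2))
}

#' Holes between roots
#'
#' Counts the 8-connected background components that do not touch the image
#' border and averages their pixel areas.
#'
#' @param mask a [RootMask-class].
#' @return Named numeric `hole_count`, `avg_size_px2`, `avg_size_mm2`;
#'   `(0, 0, 0/NA)` when there are no holes.
#' @export
holeMetrics <- function(mask) {
  m <- pixels(mask)
  sM <- pxPerMm(mask)
  bg <- label8(!m)
  holes <- if (max(bg) > 0) setdiff(seq_len(max(bg)), borderLabels(bg))
           else integer(0)
  if (!length(holes))
    return(c(hole_count = 0, avg_size_px2 = 0,
             avg_size_mm2 = .mmOrNA(0, sM, 2)))
  sizes <- tabulate(bg[!m], nbins = max(bg))[holes]
  c(hole_count = length(holes), avg_size_px2 = mean(sizes),
    avg_size_mm2 = .mmOrNA(mean(sizes), sM, 2))
}

#' Root angle frequencies and average orientation
#'
#' For every skeleton pixel, the skeleton coordinates within the 40 x 40
#' pixel locality centred on it (clipped at the borders) are collected and
#' the locality's orientation is the principal-axis direction of those
#' coordinates, expressed as the absolute angle from vertical in
#' `[0, 90]` degrees - 0 is a plumb-vertical (steep) root, 90 a horizontal
#' (shallow) one. Frequencies are the fractions of skeleton pixels whose
#' locality angle falls in `[0, 30)`, `[30, 60)` and `[60, 90]`.
#'
#' @param skel a [RadiusSkeleton-class].
#' @param window locality size in pixels (default 40).
#' @return Named numeric `steep_freq`, `medium_freq`, `shallow_freq`,
#'   `avg_orientation_deg`; zeros for an empty skeleton.
#' @export
angleFeatures <- function(skel, window = 40L) {
  s <- skeletonPixels(skel)
  if (!any(s))
    return(c(steep_freq = 0, medium_freq = 0, shallow_freq = 0,
             avg_orientation_deg = 0))
  nr <- nrow(s); nc <- ncol(s)
  idx <- which(s)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  sat <- function(m) {
    p <- rbind(0, cbind(0, m))
    apply(apply(p, 2, cumsum), 1, cumsum)  # transposed SAT
  }
  # SATs come back transposed; query with (col, row) indices
  S1 <- sat(s + 0)
  Sr <- sat(s * row(s))
  Sc <- sat(s * col(s))
  Srr <- sat(s * row(s)^2)
  Scc <- sat(s * col(s)^2)
  Src <- sat(s * row(s) * col(s))
  half <- window %/% 2L
  r1 <- pmax(rr - (half - 1L), 1L); r2 <- pmin(rr + half, nr)
  c1 <- pmax(cc - (half - 1L), 1L); c2 <- pmin(cc + half, nc)
  win <- function(S) S[cbind(c2 + 1L, r2 + 1L)] - S[cbind(c1, r2 + 1L)] -
    S[cbind(c2 + 1L, r1)] + S[cbind(c1, r1)]
  n <- win(S1)
  mr <- win(Sr) / n
  mc <- win(Sc) / n
  vr <- win(Srr) / n - mr^2
  vc <- win(Scc) / n - mc^2
  vrc <- win(Src) / n - mr * mc
  lam <- ((vr + vc) + sqrt((vr - vc)^2 + 4 * vrc^2)) / 2
  # eigenvector of the larger eigenvalue: (vrc, lam - vr), with axis-aligned
  # fallbacks when the covariance is diagonal
  er <- ifelse(abs(vrc) > 1e-12, vrc, ifelse(vr >= vc, 1, 0))
  ec <- ifelse(abs(vrc) > 1e-12, lam - vr, ifelse(vr >= vc, 0, 1))
  ang <- atan2(abs(ec), abs(er)) * 180 / pi
  ang[!is.finite(ang)] <- 0
  c(steep_freq = mean(ang < 30),
    medium_freq = mean(ang >= 30 & ang < 60),
    shallow_freq = mean(ang >= 60),
    avg_orientation_deg = mean(ang))
}
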