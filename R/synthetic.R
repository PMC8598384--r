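# Synthetic test scenes with analytic ground truth: dark wires (straight or
# arc-shaped strokes of controlled pixel width) on a bright background,
# branched root phantoms, and seeded corruption (background speckles,
# in-root bright holes). Ground truth is always computed from the *rendered*
# integer stroke width and pixel path length, so recovery tests measure
# algorithm error rather than rasterization error.

#' Specify a synthetic wire
#'
#' @param diameter_mm,length_mm physical size of the wire; the rendered
#'   stroke width is `round(diameter_mm * pxPerMm)` (at least 1) and
#'   `length_mm` is the tip-to-tip extent along the wire's path.
#' @param orientation_deg path direction, degrees from horizontal
#'   (0 = along image columns, 90 = along rows).
#' @param position centre of the wire, `c(row, col)` in px (may be
#'   fractional; width-w strokes sit on exact pixel rows when the centre row
#'   is `r0 + (w - 1) / 2`).
#' @param shape `"straight"` or `"arc"` (a circular arc subtending
#'   `arc_angle_deg`, with the same tip-to-tip path length).
#' @param arc_angle_deg subtended angle for arc wires.
#' @param endStyle `"flat"` (square-cut ends, as pliers leave on copper
#'   wire) or `"round"` (hemispherical caps). Arc wires always use round
#'   caps.
#' @return A `WireSpec` (classed list).
#' @export
wireSpec <- function(diameter_mm, length_mm, orientation_deg = 0,
                     position = c(0, 0), shape = c("straight", "arc"),
                     arc_angle_deg = 60, endStyle = c("flat", "round")) {
  stopifnot(diameter_mm > 0, length_mm > 0)
  structure(list(diameter_mm = diameter_mm, length_mm = length_mm,
                 orientation_deg = orientation_deg, position = position,
                 shape = match.arg(shape), arc_angle_deg = arc_angle_deg,
                 endStyle = match.arg(endStyle)),
            class = "WireSpec")
}

# Render one wire as a logical mask over an (nr x nc) canvas; returns the
# mask plus its rendered truth. The stroke is all pixels within
# (w - 1) / 2 of the centre path, whose tip-to-tip pixel extent is L.
.renderWire <- function(spec, pxPerMm, nr, nc) {
  w <- max(1L, round(spec$diameter_mm * pxPerMm))
  L <- max(w, round(spec$length_mm * pxPerMm))
  half <- (w - 1) / 2
  a <- (L - w) / 2                       # centre-path half-length
  th <- spec$orientation_deg * pi / 180
  dr <- sin(th); dc <- cos(th)
  ctr <- spec$position
  pad <- ceiling(half) + 1L
  if (spec$shape == "straight") {
    flat <- identical(spec$endStyle, "flat")
    aEff <- if (flat) (L - 1) / 2 else a   # flat ends: path runs tip to tip
    p1 <- ctr + aEff * c(dr, dc)
    p0 <- ctr - aEff * c(dr, dc)
    rmin <- max(1L, floor(min(p0[1], p1[1]) - pad))
    rmax <- min(nr, ceiling(max(p0[1], p1[1]) + pad))
    cmin <- max(1L, floor(min(p0[2], p1[2]) - pad))
    cmax <- min(nc, ceiling(max(p0[2], p1[2]) + pad))
    if (rmin > rmax || cmin > cmax) stop("wire lies outside the canvas")
    rr <- rep(rmin:rmax, times = cmax - cmin + 1L)
    cc <- rep(cmin:cmax, each = rmax - rmin + 1L)
    v <- cbind(rr - p0[1], cc - p0[2])
    d <- p1 - p0
    len2 <- sum(d^2)
    t <- if (len2 > 0) (v[, 1] * d[1] + v[, 2] * d[2]) / len2 else 0
    tc <- pmin(1, pmax(0, t))
    dist <- sqrt((v[, 1] - tc * d[1])^2 + (v[, 2] - tc * d[2])^2)
    if (flat) {
      inAxial <- t >= -1e-9 & t <= 1 + 1e-9
      perp <- sqrt((v[, 1] - t * d[1])^2 + (v[, 2] - t * d[2])^2)
      dist <- ifelse(inAxial, perp, Inf)     # square-cut: no caps
      pathLenPx <- L - (w - 1)               # so tip-to-tip truth is L
    } else {
      pathLenPx <- 2 * a
    }
  } else {
    phi <- spec$arc_angle_deg * pi / 180
    R <- (2 * a) / phi                    # centre-path arc length = 2a
    # arc centred so its chord midpoint sits at `ctr`, bulging "up-path"
    mid <- th + pi / 2
    O <- ctr + (R * cos(phi / 2)) * c(sin(mid), cos(mid)) * -1
    ang0 <- mid - phi / 2
    rmin <- max(1L, floor(ctr[1] - (2 * a + w))); rmax <- min(nr, ceiling(ctr[1] + 2 * a + w))
    cmin <- max(1L, floor(ctr[2] - (2 * a + w))); cmax <- min(nc, ceiling(ctr[2] + 2 * a + w))
    rr <- rep(rmin:rmax, times = cmax - cmin + 1L)
    cc <- rep(cmin:cmax, each = rmax - rmin + 1L)
    vr <- rr - O[1]; vc <- cc - O[2]
    rho <- sqrt(vr^2 + vc^2)
    ang <- atan2(vr, vc)
    rel <- (ang - ang0) %% (2 * pi)
    onArc <- rel <= phi
    e0 <- O + R * c(sin(ang0), cos(ang0))
    e1 <- O + R * c(sin(ang0 + phi), cos(ang0 + phi))
    dEnds <- pmin(sqrt((rr - e0[1])^2 + (cc - e0[2])^2),
                  sqrt((rr - e1[1])^2 + (cc - e1[2])^2))
    dist <- ifelse(onArc, abs(rho - R), dEnds)
    pathLenPx <- 2 * a
  }
  sel <- dist <= half + 1e-9
  mmask <- matrix(FALSE, nr, nc)
  mmask[cbind(rr[sel], cc[sel])] <- TRUE
  lengthPx <- pathLenPx + (w - 1)         # tip-to-tip medial extent
  list(mask = mmask, width_px = w, length_px = lengthPx,
       diameter_mm = w / pxPerMm, length_mm = lengthPx / pxPerMm)
}

#' Render a wire scene with analytic ground truth
#'
#' Draws each wire as a round-capped stroke of its rendered integer width on
#' a bright background. Truth traits treat each wire as a cylinder of the
#' rendered diameter `D = w / pxPerMm` and tip-to-tip length `L`:
#' `surface area = pi * D * L`, `volume = pi * (D/2)^2 * L`; the scene
#' average diameter is length-weighted, as for physical wire scans.
#'
#' @param specs list of [wireSpec()] objects.
#' @param pxPerMm rendering resolution (600 DPI scans are 23.62 px/mm).
#' @param backgroundLevel,wireLevel 8-bit intensities of background and wire.
#' @param canvasDim optional `c(rows, cols)`; sized to fit the wires plus a
#'   margin when omitted.
#' @param margin canvas margin in px used for auto-sizing.
#' @return A list: `image` ([RootImage-class]), `truth` (list with
#'   `total_length_mm`, `weighted_avg_diameter_mm`, `surface_area_mm2`,
#'   `volume_mm3`, `object_count`), and `wires` (per-wire data.frame of
#'   rendered widths and truths).
#' @examples
#' sc <- renderWires(list(wireSpec(1, 20, position = c(15, 30))), pxPerMm = 10)
#' sc$truth$volume_mm3
#' @export
renderWires <- function(specs, pxPerMm, backgroundLevel = 255,
                        wireLevel = 60, canvasDim = NULL, margin = 12) {
  stopifnot(pxPerMm > 0)
  if (is.null(canvasDim)) {
    ext <- vapply(specs, function(sp) {
      Lh <- round(sp$length_mm * pxPerMm) / 2 + 2
      wh <- max(1, round(sp$diameter_mm * pxPerMm)) / 2 + 2
      th <- sp$orientation_deg * pi / 180
      hr <- Lh * abs(sin(th)) + wh * abs(cos(th))
      hc <- Lh * abs(cos(th)) + wh * abs(sin(th))
      if (sp$shape == "arc") hr <- hc <- Lh + wh   # conservative for arcs
      c(sp$position[1] + hr, sp$position[2] + hc)
    }, numeric(2))
    canvasDim <- c(ceiling(max(ext[1, ], 1)) + margin,
                   ceiling(max(ext[2, ], 1)) + margin)
  }
  nr <- canvasDim[1]; nc <- canvasDim[2]
  img <- matrix(backgroundLevel, nr, nc)
  acc <- matrix(FALSE, nr, nc)
  rows <- list()
  for (sp in specs) {
    rw <- .renderWire(sp, pxPerMm, nr, nc)
    grown <- rw$mask | neighborCount8(rw$mask) > 0
    if (any(grown & acc))
      stop("wires overlap or touch; adjust positions")
    acc <- acc | rw$mask
    rows[[length(rows) + 1L]] <- data.frame(
      width_px = rw$width_px, length_px = rw$length_px,
      diameter_mm = rw$diameter_mm, length_mm = rw$length_mm,
      surface_area_mm2 = pi * rw$diameter_mm * rw$length_mm,
      volume_mm3 = pi * (rw$diameter_mm / 2)^2 * rw$length_mm)
  }
  img[acc] <- wireLevel
  wires <- do.call(rbind, rows) %||% data.frame()
  truth <- if (length(specs)) list(
    total_length_mm = sum(wires$length_mm),
    weighted_avg_diameter_mm =
      sum(wires$diameter_mm * wires$length_mm) / sum(wires$length_mm),
    surface_area_mm2 = sum(wires$surface_area_mm2),
    volume_mm3 = sum(wires$volume_mm3),
    object_count = nrow(wires))
  else list(total_length_mm = 0, weighted_avg_diameter_mm = 0,
            surface_area_mm2 = 0, volume_mm3 = 0, object_count = 0)
  list(image = rootImage(img, pxPerMm = pxPerMm), truth = truth,
       wires = wires)
}

#' Render a branched root phantom
#'
#' A horizontal main axis (round-capped stroke) with vertical laterals
#' attached below it, each wire of controlled pixel width, plus the
#' topology/length truth the generator knows by construction: lateral path
#' lengths are measured from the main axis centreline to the lateral tip.
#'
#' @param mainLengthPx,mainWidthPx tip-to-tip extent and stroke width of the
#'   main axis, in px.
#' @param laterals list of `c(offset, length, width)` triplets: attachment
#'   offset in px from the main axis' left tip, protrusion length below the
#'   main axis surface, and stroke width.
#' @param pxPerMm optional resolution carried onto the image.
#' @param backgroundLevel,wireLevel 8-bit intensities.
#' @return A list: `image`, and `truth` with `tip_count`,
#'   `branch_point_count`, `main_length_px`, `lateral_lengths_px`.
#' @export
renderBranchedRoot <- function(mainLengthPx, mainWidthPx, laterals = list(),
                               pxPerMm = numeric(), backgroundLevel = 255,
                               wireLevel = 60) {
  stopifnot(mainWidthPx >= 1, mainLengthPx > mainWidthPx)
  maxLat <- if (length(laterals))
    max(vapply(laterals, `[`, numeric(1), 2)) else 0
  maxLatW <- if (length(laterals))
    max(vapply(laterals, `[`, numeric(1), 3)) else 0
  nr <- ceiling(mainWidthPx + maxLat + maxLatW + 40)
  nc <- ceiling(mainLengthPx + 40)
  rc <- 20 + (mainWidthPx - 1) / 2       # main centreline row
  c0 <- 20                               # left tip column
  s <- 1                                  # px geometry; resolution is metadata
  mainSpec <- wireSpec(mainWidthPx, mainLengthPx, 0,
                       c(rc, c0 + (mainLengthPx - 1) / 2))
  main <- .renderWire(mainSpec, s, nr, nc)
  acc <- main$mask
  latTruth <- numeric(0)
  latAcc <- matrix(FALSE, nr, nc)
  for (lat in laterals) {
    off <- lat[1]; len <- lat[2]; w <- lat[3]
    stopifnot(w >= 1, len > 0)
    tipRow <- rc + (mainWidthPx - 1) / 2 + len
    spec <- wireSpec(w, tipRow - rc + 1, 90, c((rc + tipRow) / 2, c0 + off))
    rw <- .renderWire(spec, s, nr, nc)
    grown <- rw$mask | neighborCount8(rw$mask) > 0
    if (any(grown & latAcc)) stop("laterals overlap; adjust offsets")
    latAcc <- latAcc | rw$mask
    acc <- acc | rw$mask
    latTruth <- c(latTruth, tipRow - rc)
  }
  img <- matrix(backgroundLevel, nr, nc)
  img[acc] <- wireLevel
  list(image = rootImage(img, pxPerMm = pxPerMm),
       truth = list(tip_count = length(laterals) + 2L,
                    branch_point_count = length(laterals),
                    main_length_px = mainLengthPx - 1,
                    lateral_lengths_px = latTruth))
}

#' Corrupt a scene with speckles and holes
#'
#' Adds dark square speckles on the background (soil-particle debris) and
#' bright square holes inside roots (glare spots), at seeded random
#' positions; deterministic for a fixed seed. Speckles keep a 2 px clearance
#' from roots and holes a 1 px clearance from the root boundary, so
#' filtering/filling with thresholds at or above the corruption size restores
#' the uncorrupted segmentation exactly.
#'
#' @param img a [RootImage-class].
#' @param speckleCount,speckleSizePx number and pixel area of speckles.
#' @param holeCount,holeSizePx number and pixel area of in-root holes.
#' @param seed RNG seed (part of the fixture's identity).
#' @param threshold segmentation level used to locate root/background.
#' @return The corrupted [RootImage-class].
#' @export
corruptImage <- function(img, speckleCount = 0, speckleSizePx = 4,
                         holeCount = 0, holeSizePx = 4, seed = 1,
                         threshold = 191) {
  p <- pixels(img)
  m <- p <= threshold
  nr <- nrow(p); nc <- ncol(p)
  satOf <- function(mm) rbind(0, cbind(0, t(apply(apply(mm + 0, 2, cumsum),
                                                  1, cumsum))))
  winSum <- function(sat, side) {
    # sum over every side x side window, indexed by the top-left corner
    r <- seq_len(nr - side + 1L); c <- seq_len(nc - side + 1L)
    sat[r + side, c + side, drop = FALSE] -
      sat[r, c + side, drop = FALSE] -
      sat[r + side, c, drop = FALSE] + sat[r, c, drop = FALSE]
  }
  # place `count` side x side blocks whose surrounding `clear` window
  # satisfies `pred` on the window-sum of m; returns top-left corners
  place <- function(count, side, clear, wantFull) {
    if (clear > min(nr, nc) || count < 1) return(NULL)
    w <- winSum(satOf(m), clear)
    cand <- which(w == if (wantFull) clear^2 else 0)
    if (!length(cand)) return(NULL)
    pr <- ((cand - 1L) %% nrow(w)) + 1L
    pc <- ((cand - 1L) %/% nrow(w)) + 1L
    out <- matrix(0L, 0L, 2L)
    taken <- logical(length(cand))
    off <- (clear - side) %/% 2L
    for (i in seq_len(count)) {
      free <- which(!taken)
      if (!length(free)) break
      k <- free[sample.int(length(free), 1)]
      out <- rbind(out, c(pr[k] + off, pc[k] + off))
      taken <- taken | (abs(pr - pr[k]) <= clear + 2L &
                        abs(pc - pc[k]) <= clear + 2L)
    }
    out
  }
  withSeed(seed, {
    if (speckleCount > 0) {
      side <- max(1L, floor(sqrt(speckleSizePx)))
      sp <- place(speckleCount, side, side + 4L, FALSE)
      for (i in seq_len(nrow(sp) %||% 0L))
        p[sp[i, 1]:(sp[i, 1] + side - 1L),
          sp[i, 2]:(sp[i, 2] + side - 1L)] <- 0
    }
    if (holeCount > 0) {
      side <- max(1L, floor(sqrt(holeSizePx)))
      hl <- place(holeCount, side, side + 2L, TRUE)
      for (i in seq_len(nrow(hl) %||% 0L))
        p[hl[i, 1]:(hl[i, 1] + side - 1L),
          hl[i, 2]:(hl[i, 2] + side - 1L)] <- 255
    }
  })
  rootImage(p, pxPerMm = pxPerMm(img))
}

# American Wire Gauge diameters (mm) of the gauges used for wire validation:
# AWG 40, 32, 28, 22, 16 and 10.
.awgDiametersMm <- c(0.0799, 0.2019, 0.3211, 0.6438, 1.2908, 2.5882)

#' Seeded wire validation scenes
#'
#' Generates bright-background scenes emulating 600 DPI flatbed scans of
#' cut copper wires: each scene holds one flat-ended wire per gauge (AWG
#' 40, 32, 28, 22, 16 and 10; rendered widths about 2 to 61 px at 600 DPI)
#' laid side by side, with seeded per-wire lengths of 100-140 mm and scene
#' orientation alternating between horizontal and vertical. Trait variation
#' across scenes comes from the lengths.
#'
#' @param nScenes number of scenes.
#' @param seed RNG seed.
#' @param pxPerMm resolution (default 600 DPI).
#' @param lengthRange_mm range the per-wire lengths are drawn from.
#' @return A list of scenes as returned by [renderWires()].
#' @export
wireValidationScenes <- function(nScenes = 30, seed = 1,
                                 pxPerMm = 600 / 25.4,
                                 lengthRange_mm = c(100, 140)) {
  withSeed(seed, {
    lapply(seq_len(nScenes), function(i) {
      lens <- stats::runif(length(.awgDiametersMm), lengthRange_mm[1],
                           lengthRange_mm[2])
      vertical <- i %% 3 == 0
      widths <- pmax(1, round(.awgDiametersMm * pxPerMm))
      gap <- 16
      # integer top edge per wire so a width-w stroke covers exactly w rows
      tops <- cumsum(c(20, widths[-length(widths)] + gap))
      specs <- lapply(seq_along(widths), function(k) {
        Lpx <- round(lens[k] * pxPerMm)
        across <- tops[k] + (widths[k] - 1) / 2
        along <- 20 + (Lpx - 1) / 2
        pos <- if (vertical) c(along, across) else c(across, along)
        wireSpec(.awgDiametersMm[k], lens[k],
                 orientation_deg = if (vertical) 90 else 0, position = pos)
      })
      renderWires(specs, pxPerMm = pxPerMm)
    })
  })
}

#' Write wire scenes to disk for offline benchmarking
#'
#' Saves each scene as an 8-bit greyscale PNG (with its resolution embedded
#' as DPI) plus a `truth.csv` keyed by file name, ready for
#' [runBenchmark()].
#'
#' @param scenes list of scenes from [wireValidationScenes()] or
#'   [renderWires()].
#' @param dir output directory (created if needed).
#' @return The path of `truth.csv`, invisibly.
#' @export
writeWireScenes <- function(scenes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(scenes), function(i) {
    fn <- sprintf("scene_%02d.png", i)
    img <- scenes[[i]]$image
    png::writePNG(pixels(img) / 255, file.path(dir, fn),
                  dpi = if (length(pxPerMm(img))) pxPerMm(img) * 25.4
                        else NULL)
    tr <- scenes[[i]]$truth
    data.frame(file_name = fn,
               total_length_mm = tr$total_length_mm,
               avg_diameter_mm = tr$weighted_avg_diameter_mm,
               surface_area_mm2 = tr$surface_area_mm2,
               volume_mm3 = tr$volume_mm3,
               object_count = tr$object_count)
  })
  truth <- do.call(rbind, rows)
  path <- file.path(dir, "truth.csv")
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
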