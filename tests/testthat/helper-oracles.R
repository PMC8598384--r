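# Independent oracles and fixture builders used across the suite. These
# deliberately use the dumbest correct formulation (exhaustive search,
# one-at-a-time editing) and never call the code paths they check.

# O(n^2) exact Euclidean distance transform: for every root pixel, search
# every background pixel.
bruteForceEDT <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  bg <- which(!m, arr.ind = TRUE)
  if (!nrow(bg)) return(out + Inf * m)
  fg <- which(m, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# Pruning oracle: repeat single passes, deleting exactly one eligible
# branch-to-tip segment per iteration (shortest length - radius first, ties
# by branch row then column), reclassifying from scratch every time.
prunedByOracle <- function(skel, thresholdPx) {
  rad <- radiusMap(skel)
  repeat {
    sk <- new("RadiusSkeleton", radius = rad, pxPerMm = numeric())
    segs <- rootSegments(classifyPixels(sk))
    cand <- list()
    for (sg in segs) {
      if (!setequal(sg$end_types, c("TIP", "BRANCH"))) next
      bEnd <- if (sg$end_types[1] == "BRANCH") 1L else nrow(sg$path)
      bpix <- sg$path[bEnd, ]
      r <- rad[bpix[1], bpix[2]]
      if (sg$length_px <= r + thresholdPx)
        cand[[length(cand) + 1L]] <- list(sg = sg, score = sg$length_px - r,
                                          b = bpix, bEnd = bEnd)
    }
    if (!length(cand)) break
    ord <- order(vapply(cand, `[[`, numeric(1), "score"),
                 vapply(cand, function(x) x$b[1], numeric(1)),
                 vapply(cand, function(x) x$b[2], numeric(1)))
    pick <- cand[[ord[1]]]
    drop <- pick$sg$path[-pick$bEnd, , drop = FALSE]
    rad[drop] <- 0
    rad[!rootquant:::.collapseCorners(rad > 0)] <- 0
  }
  rad > 0
}

# Independent Ramer-Douglas-Peucker on an open polyline, written
# recursively (the package version is stack-based).
rdpReference <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  d <- b - a
  len <- sqrt(sum(d^2))
  dist <- if (len == 0) sqrt(rowSums(sweep(pts, 2, a)^2))
          else abs((pts[, 1] - a[1]) * d[2] - (pts[, 2] - a[2]) * d[1]) / len
  k <- which.max(dist)
  if (dist[k] <= tol) return(pts[c(1L, n), , drop = FALSE])
  left <- rdpReference(pts[1:k, , drop = FALSE], tol)
  right <- rdpReference(pts[k:n, , drop = FALSE], tol)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

# Random blob mask: union of a few rectangles and discs on a small grid,
# guaranteed to keep at least one background pixel.
randomMask <- function(nr = 30, nc = 30, nBlobs = 3) {
  m <- matrix(FALSE, nr, nc)
  for (b in seq_len(nBlobs)) {
    if (stats::runif(1) < 0.5) {
      r0 <- sample(nr - 4, 1); c0 <- sample(nc - 4, 1)
      h <- sample(3:min(10, nr - r0), 1); w <- sample(3:min(10, nc - c0), 1)
      m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
    } else {
      cr <- stats::runif(1, 4, nr - 3); cc <- stats::runif(1, 4, nc - 3)
      rad <- stats::runif(1, 1.5, 5)
      px <- which(outer(seq_len(nr), seq_len(nc),
                        function(i, j) (i - cr)^2 + (j - cc)^2 <= rad^2))
      m[px] <- TRUE
    }
  }
  m[1, ] <- FALSE; m[nr, ] <- FALSE; m[, 1] <- FALSE; m[, nc] <- FALSE
  m
}

# Random small skeleton: the pipeline's own skeleton of a random blob mask
# (used as an arbitrary-but-valid RadiusSkeleton input for pruning tests).
randomSkeleton <- function(nr = 30, nc = 30, nBlobs = 3) {
  m <- randomMask(nr, nc, nBlobs)
  while (!any(m)) m <- randomMask(nr, nc, nBlobs)
  buildSkeleton(rootMask(m))
}

# Count of 8-connected components.
nComponents <- function(m) max(rootquant:::label8(m), 0L)

# Independent cycle rank (edges - vertices + components) of a pixel set
# under 8-adjacency.
cycleRankOracle <- function(s) {
  sh <- function(dr, dc) {
    out <- matrix(FALSE, nrow(s), ncol(s))
    r1 <- max(1, 1 - dr):min(nrow(s), nrow(s) - dr)
    c1 <- max(1, 1 - dc):min(ncol(s), ncol(s) - dc)
    out[r1, c1] <- s[r1 + dr, c1 + dc]
    out
  }
  E <- sum(s & sh(0, 1)) + sum(s & sh(1, 0)) + sum(s & sh(1, 1)) +
    sum(s & sh(1, -1))
  E - sum(s) + nComponents(s)
}

# Build a RadiusSkeleton directly from a pixel path/set with given radii
# (bypasses buildSkeleton, for feature-level unit tests).
skeletonFromPixels <- function(rc, radii, dim, pxPerMm = numeric()) {
  rad <- matrix(0, dim[1], dim[2])
  rad[rc] <- radii
  new("RadiusSkeleton", radius = rad, pxPerMm = as.numeric(pxPerMm))
}

# Minimal uncompressed 8-bit greyscale BMP writer (bottom-up rows) used to
# exercise the BMP reader; `ppm` is pixels per metre.
writeGreyBMP <- function(px, path, ppm = 0L) {
  h <- nrow(px); w <- ncol(px)
  rowBytes <- ((w + 3L) %/% 4L) * 4L
  palette <- as.raw(as.vector(rbind(0:255, 0:255, 0:255, rep(0, 256))))
  offset <- 14L + 40L + 1024L
  fileSize <- offset + rowBytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(c(fileSize, 0L, offset)), con, size = 4)
  writeBin(40L, con, size = 4)
  writeBin(as.integer(c(w, h)), con, size = 4)
  writeBin(c(1L, 8L), con, size = 2)
  writeBin(as.integer(c(0L, rowBytes * h, ppm, ppm, 256L, 0L)), con,
           size = 4)
  writeBin(palette, con)
  for (r in rev(seq_len(h))) {
    row <- as.raw(px[r, ])
    writeBin(c(row, rep(as.raw(0), rowBytes - w)), con)
  }
  invisible(path)
}
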