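# Contour extraction on binary masks. Contours are traced on root pixels
# with the Moore-neighbour algorithm in pixel-centre coordinates: the outer
# boundary of every 8-connected root component plus one inner boundary per
# enclosed hole. These closed pixel paths drive both the perimeter trait and
# Ramer-Douglas-Peucker edge smoothing.

# Moore-neighbour tracing. `start` is c(row, col); `back` is the background
# pixel we conceptually arrived from. Stops with Jacob's criterion (start
# pixel re-entered from the same backtrack). Returns an n x 2 matrix of the
# closed boundary path (first pixel not repeated at the end).
.traceBoundary <- function(m, start, back) {
  nr <- nrow(m); nc <- ncol(m)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc
  # clockwise ring around a pixel, starting at E
  ring <- matrix(c(0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L, 0L, -1L,
                   -1L, -1L, -1L, 0L, -1L, 1L), ncol = 2L, byrow = TRUE)
  ringIndex <- function(d) which(ring[, 1] == d[1] & ring[, 2] == d[2])
  maxSteps <- 4L * (sum(m) + 8L)
  path <- matrix(0L, maxSteps, 2L)
  np <- 0L
  cur <- start
  bk <- back
  firstState <- NULL
  for (step in seq_len(maxSteps)) {
    np <- np + 1L
    path[np, ] <- cur
    ki <- ringIndex(bk - cur)
    found <- FALSE
    prev <- bk
    for (j in seq_len(8)) {
      k <- ((ki + j - 1L) %% 8L) + 1L     # clockwise from backtrack
      cand <- cur + ring[k, ]
      if (inside(cand[1], cand[2]) && m[cand[1], cand[2]]) {
        found <- TRUE
        bk <- prev
        cur <- cand
        break
      }
      prev <- cand
    }
    if (!found) break                      # isolated pixel
    state <- c(cur, bk)
    if (is.null(firstState)) {
      firstState <- state
    } else if (all(state == firstState)) break
  }
  path[seq_len(np), , drop = FALSE]
}

# All contours of a mask: per root component the outer boundary, plus the
# inner boundary around every enclosed hole. Returns a list of lists with
# elements `path` (n x 2) and `type` ("outer"/"inner"), plus the component id.
maskContours <- function(m) {
  out <- list()
  if (!any(m)) return(out)
  lab <- label8(m)
  for (id in seq_len(max(lab))) {
    compIdx <- which(lab == id)
    r0 <- ((compIdx - 1L) %% nrow(m)) + 1L
    c0 <- ((compIdx - 1L) %/% nrow(m)) + 1L
    o <- order(r0, c0)[1]                 # topmost, then leftmost
    start <- c(r0[o], c0[o])
    path <- .traceBoundary(lab == id, start, start + c(0L, -1L))
    out[[length(out) + 1L]] <- list(path = path, type = "outer",
                                    component = id)
  }
  # holes: 8-connected background components that do not touch the border
  bg <- label8(!m)
  if (max(bg) > 0) {
    borders <- setdiff(seq_len(max(bg)), borderLabels(bg))
    for (id in borders) {
      holeIdx <- which(bg == id)
      r0 <- ((holeIdx - 1L) %% nrow(m)) + 1L
      c0 <- ((holeIdx - 1L) %/% nrow(m)) + 1L
      o <- order(r0, c0)[1]
      # the pixel immediately above the hole's topmost pixel is root
      start <- c(r0[o] - 1L, c0[o])
      comp <- lab[start[1], start[2]]
      path <- .traceBoundary(lab == comp, start, c(r0[o], c0[o]))
      out[[length(out) + 1L]] <- list(path = path, type = "inner",
                                      component = comp)
    }
  }
  out
}

# Euclidean length of a closed pixel path (unit and sqrt(2) steps, including
# the closing step). A single-pixel path has length 0.
closedPathLength <- function(path) {
  n <- nrow(path)
  if (n < 2L) return(0)
  nxt <- rbind(path[-1L, , drop = FALSE], path[1L, , drop = FALSE])
  sum(sqrt(rowSums((nxt - path)^2)))
}

# ---------------------------------------------------------------------------
# Ramer-Douglas-Peucker simplification
# ---------------------------------------------------------------------------

# Perpendicular distance of points to the segment a-b (falls back to the
# distance to a when a == b).
.perpDist <- function(pts, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(pts, 2, a)^2)))
  abs((pts[, 1] - a[1]) * d[2] - (pts[, 2] - a[2]) * d[1]) / sqrt(len2)
}

# RDP on an open polyline (keeps endpoints).
rdpOpen <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- rng[1]; j <- rng[2]
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- .perpDist(pts[mid, , drop = FALSE], pts[i, ], pts[j, ])
    k <- which.max(d)
    if (d[k] > tol) {
      keep[mid[k]] <- TRUE
      stack <- c(stack, list(c(i, mid[k])), list(c(mid[k], j)))
    }
  }
  pts[keep, , drop = FALSE]
}

# RDP on a closed contour: anchor at the first vertex and the vertex
# farthest from it, simplify the two arcs separately.
rdpClosed <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 3L) return(pts)
  dist0 <- rowSums(sweep(pts, 2, pts[1, ])^2)
  split <- which.max(dist0)
  if (split <= 1L) return(pts)
  arc1 <- rdpOpen(pts[1:split, , drop = FALSE], tol)
  arc2 <- rdpOpen(pts[c(split:n, 1L), , drop = FALSE], tol)
  rbind(arc1, arc2[-c(1L, nrow(arc2)), , drop = FALSE])
}

# ---------------------------------------------------------------------------
# Polygon rasterization (pixel centres)
# ---------------------------------------------------------------------------

# Integer pixels of the closed polygon outline (Bresenham along each edge).
.polyOutline <- function(poly) {
  n <- nrow(poly)
  segs <- lapply(seq_len(n), function(i) {
    a <- poly[i, ]; b <- poly[(i %% n) + 1L, ]
    .bresenham(a, b)
  })
  unique(do.call(rbind, segs))
}

.bresenham <- function(a, b) {
  dr <- b[1] - a[1]; dc <- b[2] - a[2]
  n <- max(abs(dr), abs(dc))
  if (n == 0) return(matrix(a, 1L, 2L))
  t <- seq(0, 1, length.out = n + 1L)
  cbind(round(a[1] + t * dr), round(a[2] + t * dc))
}

# Even-odd point-in-polygon test for pixel centres, vectorised over pixels.
# Half-open crossing rule; boundary handling is delegated to the outline set.
.pointsInPoly <- function(rr, cc, poly) {
  n <- nrow(poly)
  inside <- logical(length(rr))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > rr) != (yj > rr))
    if (any(crosses)) {
      xint <- xi + (rr - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (cc < xint))
    }
    j <- i
  }
  inside
}

# Rasterize one component from its simplified outer polygon and hole
# polygons: fill the outer polygon (boundary included via its outline),
# carve hole interiors but keep hole-boundary pixels (the traced inner
# contours sit on root pixels).
rasterizePolyComponent <- function(outer, holes, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  rmin <- max(1L, floor(min(outer[, 1]))); rmax <- min(nr, ceiling(max(outer[, 1])))
  cmin <- max(1L, floor(min(outer[, 2]))); cmax <- min(nc, ceiling(max(outer[, 2])))
  rr <- rep(rmin:rmax, times = cmax - cmin + 1L)
  cc <- rep(cmin:cmax, each = rmax - rmin + 1L)
  inside <- .pointsInPoly(rr, cc, outer)
  m[cbind(rr[inside], cc[inside])] <- TRUE
  ol <- .polyOutline(outer)
  ok <- ol[, 1] >= 1 & ol[, 1] <= nr & ol[, 2] >= 1 & ol[, 2] <= nc
  m[ol[ok, , drop = FALSE]] <- TRUE
  for (h in holes) {
    hin <- .pointsInPoly(rr, cc, h)
    hol <- .polyOutline(h)
    m[cbind(rr[hin], cc[hin])] <- FALSE
    hok <- hol[, 1] >= 1 & hol[, 1] <= nr & hol[, 2] >= 1 & hol[, 2] <= nc
    m[hol[hok, , drop = FALSE]] <- TRUE
  }
  m
}
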