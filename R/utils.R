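# Low-level pixel-grid helpers shared across modules. Matrices are indexed
# [row, col] with row 1 at the top of the image, so "depth" grows with row.

# Fixed 8-neighbour order used wherever ties must break deterministically:
# E, NE, N, NW, W, SW, S, SE (offsets are c(drow, dcol)).
.nbOffsets <- matrix(c(
   0L,  1L,
  -1L,  1L,
  -1L,  0L,
  -1L, -1L,
   0L, -1L,
   1L, -1L,
   1L,  0L,
   1L,  1L), ncol = 2L, byrow = TRUE,
  dimnames = list(c("E", "NE", "N", "NW", "W", "SW", "S", "SE"), NULL))

# result[i, j] == m[i + dr, j + dc], `fill` outside the image.
shiftMat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
  if (r1 <= r2 && c1 <= c2)
    out[r1:r2, c1:c2] <- m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  out
}

# Number of TRUE 8-neighbours per pixel.
neighborCount8 <- function(s) {
  n <- matrix(0L, nrow(s), ncol(s))
  for (k in seq_len(8))
    n <- n + shiftMat(s, .nbOffsets[k, 1], .nbOffsets[k, 2], FALSE)
  n
}

# 8-connected component labelling. EBImage::bwlabel() is 4-connected, so
# labels that meet diagonally are merged with a small union-find pass.
label8 <- function(px) {
  m <- px != 0
  if (!any(m)) return(matrix(0L, nrow(m), ncol(m)))
  L <- EBImage::imageData(EBImage::bwlabel(m + 0))
  storage.mode(L) <- "integer"
  k <- max(L)
  parent <- seq_len(k)
  findp <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (s in list(c(1L, 1L), c(1L, -1L))) {
    b <- shiftMat(L, s[1], s[2], 0L)
    sel <- L > 0L & b > 0L & L != b
    if (any(sel)) {
      prs <- unique(cbind(L[sel], b[sel]))
      for (i in seq_len(nrow(prs))) {
        ra <- findp(prs[i, 1]); rb <- findp(prs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_len(k), findp, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- matrix(0L, nrow(m), ncol(m))
  out[m] <- dense[L[m]]
  out
}

# Labels of components that touch the image border.
borderLabels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Convert an area threshold to px^2. Sizes are interpreted in mm^2 whenever a
# resolution is available (matching how scanner workflows state them) and in
# px^2 otherwise.
areaToPx2 <- function(size, units, pxPerMm) {
  units <- match.arg(units, c("px2", "mm2"))
  if (units == "mm2") {
    if (length(pxPerMm) != 1L || !is.finite(pxPerMm) || pxPerMm <= 0)
      stop("an area in mm^2 requires a positive pixels-per-mm resolution")
    size * pxPerMm^2
  } else size
}

`%||%` <- function(a, b) if (is.null(a)) b else a
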