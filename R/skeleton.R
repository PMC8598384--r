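# Medial-axis construction. The skeleton is built in four stages:
# an exact Euclidean distance transform; ridge detection (a pixel whose
# distance value dominates a pair of opposite neighbours); steepest-ascent
# walks that connect detached ridge fragments (laterals whose ridge dies on
# the flank of a thicker parent); and Guo-Hall thinning down to one-pixel
# width. Radii are the distance-map values at the surviving pixels.

#' Exact Euclidean distance transform
#'
#' For every root pixel, the Euclidean distance (in px, centre to centre) to
#' the nearest background pixel; 0 on background. Exact, not a chamfer
#' approximation.
#'
#' @param mask a [RootMask-class].
#' @return A numeric matrix of distances with the mask's shape.
#' @export
distanceTransform <- function(mask) {
  stopifnot(is(mask, "RootMask"))
  m <- pixels(mask)
  if (!any(m)) return(matrix(0, nrow(m), ncol(m)))
  if (all(m))
    warning("mask has no background pixels; distances are infinite")
  d <- EBImage::imageData(EBImage::distmap(m + 0, metric = "euclidean"))
  matrix(as.numeric(d), nrow(m), ncol(m))
}

#' Detect ridges of a distance map
#'
#' A root pixel is a ridge pixel when its distance value exceeds both
#' neighbours of at least one opposite-direction pair (E/W, N/S, NE/SW,
#' NW/SE). Tie handling is what separates true medial pixels from the
#' sqrt-of-integers fluctuations of an exact distance map along curved
#' boundaries:
#' * axis pairs (E/W, N/S) fire on a strict maximum of any size, or on a
#'   tie with one neighbour while beating the other by a full pixel - the
#'   signature of the two-pixel plateau of an even-width root, whose flanks
#'   sit exactly 1 px lower. Fractional-excess ties (concentric arcs around
#'   rounded ends) are rejected.
#' * diagonal pairs (NE/SW, NW/SE) require an excess of at least half a
#'   pixel on both sides: a genuine diagonal ridge (corner bisector)
#'   dominates by about 1 px, parity noise by less than 0.5.
#'
#' Out-of-image neighbours count as background.
#'
#' @param dmap a distance map from [distanceTransform()].
#' @return A logical matrix marking ridge pixels.
#' @export
detectRidges <- function(dmap) {
  v <- dmap
  margin <- 0.5
  tieExcess <- 1 - 1e-9
  pair <- function(dr, dc, strict) {
    a <- shiftMat(v, dr, dc, 0)
    b <- shiftMat(v, -dr, -dc, 0)
    if (strict) v > a + margin & v > b + margin
    else (v > a & v > b) |
      (v == a & v - b >= tieExcess) | (v == b & v - a >= tieExcess)
  }
  ridge <- pair(0, 1, FALSE) | pair(1, 0, FALSE) |
    pair(-1, 1, TRUE) | pair(1, 1, TRUE)
  ridge & v > 0
}

#' Connect ridge fragments by steepest ascent
#'
#' Ridges on a lateral root stop short of the parent's ridge because the
#' distance map keeps climbing across the junction. From every endpoint of
#' every ridge fragment (a skeleton pixel with at most one skeleton
#' neighbour), walk repeatedly to the 8-neighbour with the largest distance
#' value (ties broken in the fixed order E, NE, N, NW, W, SW, S, SE; equal
#' values continue the walk across plateaus), adding the visited pixels,
#' until an existing skeleton pixel is reached or the ascent stalls. Mask
#' components whose ridge set is empty are seeded with their distance-map
#' maximum. If fragments remain detached afterwards (degenerate plateaus), a
#' deterministic in-mask bridge joins them, so the result has exactly one
#' skeleton component per mask component.
#'
#' @param dmap a distance map.
#' @param ridges logical matrix of ridge pixels (subset of root pixels).
#' @return A logical matrix: the connected (possibly still two-pixel-wide)
#'   skeleton.
#' @export
connectRidges <- function(dmap, ridges) {
  nr <- nrow(dmap); nc <- ncol(dmap)
  root <- dmap > 0
  skel <- ridges & root
  if (!any(root)) return(skel)
  maskLab <- label8(root)
  nComp <- max(maskLab)
  compSize <- tabulate(maskLab[root], nbins = nComp)
  # seed components with no ridge at their distance-map maximum
  withRidge <- unique(maskLab[skel])
  for (id in setdiff(seq_len(nComp), withRidge)) {
    idx <- which(maskLab == id)
    skel[idx[which.max(dmap[idx])]] <- TRUE
  }
  nbr <- function(i) {
    r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
    rr <- r + .nbOffsets[, 1]; cc <- c + .nbOffsets[, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    (cc[ok] - 1L) * nr + rr[ok]
  }
  # ridge fragments are clusters; connections form a forest over clusters
  # (union-find), so the walks never close a cycle that was not already
  # present inside a single fragment
  clus <- label8(skel)
  nClus <- max(clus)
  parentUF <- seq_len(nClus)
  findUF <- function(x) {
    while (parentUF[x] != x) {
      parentUF[x] <<- parentUF[parentUF[x]]
      x <- parentUF[x]
    }
    x
  }
  endpoints <- which(skel & neighborCount8(skel) <= 1L)
  for (e in endpoints) {
    own <- findUF(clus[e])
    cur <- e
    path <- integer(0)
    visited <- cur
    target <- 0L
    cap <- compSize[maskLab[e]]
    for (step in seq_len(cap)) {
      cand <- nbr(cur)
      cand <- cand[root[cand] & !(cand %in% visited)]
      if (!length(cand)) break
      nxt <- cand[which.max(dmap[cand])]
      if (dmap[nxt] < dmap[cur]) break          # ascent stalls
      if (skel[nxt]) {                          # stepped onto a fragment
        target <- clus[nxt]
        break
      }
      # curling up against the walk's own path would close a loop: stall
      prevPx <- cur
      selfAdj <- nbr(nxt)
      selfAdj <- selfAdj[selfAdj != prevPx & (selfAdj %in% visited)]
      if (length(selfAdj)) break
      path <- c(path, nxt)
      visited <- c(visited, nxt)
      cur <- nxt
      # a touched fragment also counts as reached (running on alongside it
      # would lay a redundant parallel path)
      touch <- nbr(cur)
      touch <- touch[skel[touch] & !(touch %in% visited)]
      if (length(touch)) {
        target <- clus[touch[1]]
        break
      }
    }
    if (target > 0L) {
      tgt <- findUF(target)
      if (tgt == own) next                      # already connected: discard
      if (length(path)) {
        skel[path] <- TRUE
        clus[path] <- own
      }
      parentUF[max(own, tgt)] <- min(own, tgt)
    }
    # stalled walks are discarded: their pixels would only add spurs that
    # connect nothing
  }
  # guarantee one skeleton component per mask component
  skLab <- label8(skel)
  for (id in seq_len(nComp)) {
    repeat {
      clusters <- unique(skLab[skel & maskLab == id])
      if (length(clusters) <= 1L) break
      seedCluster <- clusters[which.min(vapply(clusters, function(cl)
        min(which(skLab == cl)), numeric(1)))]
      # BFS through the mask component from the seed cluster to any other
      seedPx <- which(skLab == seedCluster & maskLab == id)
      queue <- integer(sum(maskLab == id))
      queue[seq_along(seedPx)] <- seedPx
      head <- 1L; tail <- length(seedPx)
      parent <- integer(nr * nc)
      seen <- logical(nr * nc)
      seen[seedPx] <- TRUE
      hit <- 0L
      while (head <= tail && hit == 0L) {
        q <- queue[head]; head <- head + 1L
        for (nb in nbr(q)) {
          if (!root[nb] || seen[nb]) next
          seen[nb] <- TRUE
          parent[nb] <- q
          if (skel[nb]) { hit <- nb; break }
          tail <- tail + 1L
          queue[tail] <- nb
        }
      }
      if (hit == 0L) break                      # should not happen
      p <- hit
      while (p != 0L && !(skLab[p] == seedCluster && skel[p])) {
        skel[p] <- TRUE
        p <- parent[p]
      }
      skLab <- label8(skel)
    }
  }
  skel
}

#' Guo-Hall thinning to one-pixel width
#'
#' The standard two-subiteration Guo-Hall scheme, applied until stable. It
#' preserves 8-connectivity while eroding the two-pixel-wide stretches that
#' ridge detection can produce. A conservative clean-up pass then deletes
#' any remaining pixel completing a fully occupied 2x2 block, but only where
#' deletion keeps the local neighbourhood connected, so no such block
#' survives and component counts are unchanged.
#'
#' @param px logical matrix of skeleton pixels.
#' @return The thinned logical matrix.
#' @export
thinSkeleton <- function(px) {
  s <- px
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      del <- .guoHallDeletions(s, sub)
      if (any(del)) {
        s[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  .collapseCorners(.clear2x2(s))
}

# Remove redundant pixels that ride on an otherwise intact path:
# * a pixel with exactly two neighbours that are themselves 8-adjacent is a
#   staircase/triangle corner; deleting it straightens the path;
# * a pixel with exactly three neighbours that are consecutive collinear
#   pixels (a straight 3-run in a row, column or diagonal) is a bump on a
#   straight stretch - typical where a connecting walk lands against the
#   backbone - and contributes only triangle fans.
# Deletion preserves connectivity in both cases. Larger cycles are
# untouched: their pixels' neighbours are not mutually adjacent.
.collapseCorners <- function(s, cand = NULL) {
  nr <- nrow(s); nc <- ncol(s)
  straightRun <- function(ra, ca) {
    o <- order(ra, ca)
    ra <- ra[o]; ca <- ca[o]
    (all(ra == ra[1]) && all(diff(sort(ca)) == 1L)) ||
      (all(ca == ca[1]) && all(diff(ra) == 1L)) ||
      (all(diff(ra) == 1L) && (all(diff(ca) == 1L) || all(diff(ca) == -1L)))
  }
  nbrOf <- function(i) {
    r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
    rr <- r + .nbOffsets[, 1]; cc <- c + .nbOffsets[, 2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    (cc[ok] - 1L) * nr + rr[ok]
  }
  if (is.null(cand)) {
    nb <- neighborCount8(s)
    cand <- which(s & (nb == 2L | nb == 3L))
  } else {
    cand <- sort(cand[s[cand]])
  }
  repeat {
    deleted <- integer(0)
    for (i in cand) {
      if (!s[i]) next
      j <- nbrOf(i)
      j <- j[s[j]]
      ra <- ((j - 1L) %% nr) + 1L; ca <- ((j - 1L) %/% nr) + 1L
      drop <- if (length(j) == 2L)
        max(abs(ra[1] - ra[2]), abs(ca[1] - ca[2])) == 1L
      else if (length(j) == 3L) straightRun(ra, ca)
      else FALSE
      if (drop) {
        s[i] <- FALSE
        deleted <- c(deleted, i)
      }
    }
    if (!length(deleted)) break
    # only pixels near a deletion can become newly collapsible
    cand <- unique(unlist(lapply(deleted, nbrOf)))
    cand <- cand[s[cand]]
  }
  s
}

.guoHallDeletions <- function(s, sub) {
  p2 <- shiftMat(s, -1, 0, FALSE); p3 <- shiftMat(s, -1, 1, FALSE)
  p4 <- shiftMat(s, 0, 1, FALSE);  p5 <- shiftMat(s, 1, 1, FALSE)
  p6 <- shiftMat(s, 1, 0, FALSE);  p7 <- shiftMat(s, 1, -1, FALSE)
  p8 <- shiftMat(s, 0, -1, FALSE); p9 <- shiftMat(s, -1, -1, FALSE)
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
       (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  N <- pmin(N1, N2)
  m <- if (sub == 0) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
  s & C == 1 & N >= 2 & N <= 3 & !m
}

# Delete pixels stuck in fully occupied 2x2 blocks when removal preserves
# the connectivity of their 8-neighbourhood (and the pixel is no endpoint).
.clear2x2 <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  repeat {
    blk <- s & shiftMat(s, 0, 1, FALSE) & shiftMat(s, 1, 0, FALSE) &
      shiftMat(s, 1, 1, FALSE)
    if (!any(blk)) break
    members <- blk | shiftMat(blk, 0, -1, FALSE) |
      shiftMat(blk, -1, 0, FALSE) | shiftMat(blk, -1, -1, FALSE)
    cand <- which(members & s)
    deleted <- FALSE
    for (i in cand) {
      if (!s[i]) next
      r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
      # still inside a full 2x2?
      inBlock <- FALSE
      for (dr in c(-1L, 0L)) for (dc in c(-1L, 0L)) {
        rs <- r + dr; cs <- c + dc
        if (rs >= 1L && rs + 1L <= nr && cs >= 1L && cs + 1L <= nc &&
            s[rs, cs] && s[rs + 1L, cs] && s[rs, cs + 1L] &&
            s[rs + 1L, cs + 1L]) inBlock <- TRUE
      }
      if (!inBlock) next
      if (.isSimplePoint(s, r, c)) {
        s[r, c] <- FALSE
        deleted <- TRUE
      }
    }
    if (!deleted) break
  }
  s
}

# Simple-point test on the 8-neighbourhood ring: deletion preserves local
# connectivity iff the foreground ring pixels form one connected arc, the
# pixel is not an endpoint, and it has at least one orthogonal background
# neighbour.
.isSimplePoint <- function(s, r, c) {
  nr <- nrow(s); nc <- ncol(s)
  val <- function(dr, dc) {
    rr <- r + dr; cc <- c + dc
    rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && s[rr, cc]
  }
  # ring order: E NE N NW W SW S SE (positions 1..8)
  ring <- c(val(0, 1), val(-1, 1), val(-1, 0), val(-1, -1),
            val(0, -1), val(1, -1), val(1, 0), val(1, 1))
  nOn <- sum(ring)
  if (nOn < 2L) return(FALSE)
  if (!any(!ring[c(1, 3, 5, 7)])) return(FALSE)  # no orthogonal background
  # two ring cells are adjacent when their offsets differ by at most 1 in
  # both coordinates (true 8-adjacency on the pixel grid)
  adj <- function(i, j) {
    max(abs(.nbOffsets[i, 1] - .nbOffsets[j, 1]),
        abs(.nbOffsets[i, 2] - .nbOffsets[j, 2])) == 1L
  }
  on <- which(ring)
  compId <- seq_along(on)
  repeat {
    merged <- FALSE
    for (a in seq_along(on)) for (b in seq_along(on)) {
      if (compId[a] != compId[b] && adj(on[a], on[b])) {
        compId[compId == max(compId[a], compId[b])] <-
          min(compId[a], compId[b])
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  length(unique(compId)) == 1L
}

# Break "false loops": skeleton cycles that enclose no background pixel.
# The medial axis of a simply-connected region is a tree, so any extra
# cycle (beyond the mask's holes) is an artifact of discrete ridge
# geometry - typically crossing bisector chains near rounded ends. Each
# false cycle is broken at its lowest-radius degree-2 pixel (ties by
# lexicographic position), after which corner collapse re-tidies the path.
# Cycles that enclose background (roots crossing or annular shapes) are
# genuine and kept.
.suppressFalseLoops <- function(skel, mask, dmap) {
  holes <- {
    bg <- label8(!mask)
    if (max(bg) > 0) length(setdiff(seq_len(max(bg)), borderLabels(bg)))
    else 0L
  }
  nr <- nrow(skel)
  cycleRank <- function(s) {
    V <- sum(s)
    E <- sum(s & shiftMat(s, 0, 1, FALSE)) + sum(s & shiftMat(s, 1, 0, FALSE)) +
      sum(s & shiftMat(s, 1, 1, FALSE)) + sum(s & shiftMat(s, 1, -1, FALSE))
    E - V + max(label8(s))
  }
  guard <- cycleRank(skel) + 10L
  for (iter in seq_len(max(guard, 0L))) {
    if (cycleRank(skel) <= holes) break
    idx <- which(skel)
    if (!length(idx)) break
    id <- match(seq_len(length(skel)), idx)   # pixel -> node index
    nbList <- function(i) {
      r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
      rr <- r + .nbOffsets[, 1]; cc <- c + .nbOffsets[, 2]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(skel)
      j <- (cc[ok] - 1L) * nr + rr[ok]
      j[skel[j]]
    }
    parent <- integer(length(idx))            # BFS forest (0 = root)
    depth <- integer(length(idx))
    seen <- logical(length(idx))
    extraU <- integer(0); extraV <- integer(0) # non-tree edges (node ids)
    queue <- integer(length(idx))
    for (start in seq_along(idx)) {
      if (seen[start]) next
      seen[start] <- TRUE
      queue[1L] <- start
      head <- 1L; tail <- 1L
      while (head <= tail) {
        u <- queue[head]; head <- head + 1L
        for (p in nbList(idx[u])) {
          vtx <- id[p]
          if (!seen[vtx]) {
            seen[vtx] <- TRUE
            parent[vtx] <- u
            depth[vtx] <- depth[u] + 1L
            tail <- tail + 1L
            queue[tail] <- vtx
          } else if (vtx != parent[u] && u < vtx) {
            extraU <- c(extraU, u); extraV <- c(extraV, vtx)
          }
        }
      }
    }
    extra <- cbind(extraU, extraV)
    if (!nrow(extra)) break
    broke <- FALSE
    for (k in seq_len(nrow(extra))) {
      u <- extra[k, 1]; w <- extra[k, 2]
      pu <- u; pw <- w
      pathU <- u; pathW <- w
      while (depth[pu] > depth[pw]) { pu <- parent[pu]; pathU <- c(pathU, pu) }
      while (depth[pw] > depth[pu]) { pw <- parent[pw]; pathW <- c(pathW, pw) }
      while (pu != pw) {
        pu <- parent[pu]; pathU <- c(pathU, pu)
        pw <- parent[pw]; pathW <- c(pathW, pw)
      }
      cyc <- c(pathU, rev(pathW[-length(pathW)]))
      px <- idx[cyc]
      rr <- ((px - 1L) %% nr) + 1L; cc <- ((px - 1L) %/% nr) + 1L
      # enclosure test: any background pixel strictly inside the polygon?
      rmin <- min(rr); rmax <- max(rr); cmin <- min(cc); cmax <- max(cc)
      sub <- !mask[rmin:rmax, cmin:cmax, drop = FALSE]
      enclosed <- FALSE
      if (any(sub)) {
        bgi <- which(sub)
        br <- ((bgi - 1L) %% nrow(sub)) + rmin
        bc <- ((bgi - 1L) %/% nrow(sub)) + cmin
        enclosed <- any(.pointsInPoly(br, bc, cbind(rr, cc)))
      }
      if (enclosed) next
      nbCount <- neighborCount8(skel)
      cand <- px[nbCount[px] == 2L]
      if (!length(cand)) {
        # dense triangle meshes have no degree-2 pixel; fall back to any
        # simple point on the cycle (deletion provably keeps connectivity)
        simple <- vapply(px, function(i)
          .isSimplePoint(skel, ((i - 1L) %% nr) + 1L,
                         ((i - 1L) %/% nr) + 1L), logical(1))
        cand <- px[simple]
      }
      if (!length(cand)) next
      o <- order(dmap[cand], ((cand - 1L) %% nr) + 1L,
                 ((cand - 1L) %/% nr) + 1L)
      skel[cand[o[1]]] <- FALSE
      skel <- .collapseCorners(skel)
      broke <- TRUE
      break
    }
    if (!broke) break
  }
  skel
}

#' Build a radius-annotated skeleton from a mask
#'
#' Composition of [distanceTransform()], [detectRidges()],
#' [connectRidges()] and [thinSkeleton()]; every surviving pixel carries the
#' distance-map value at its position as the local root radius.
#'
#' @param mask a [RootMask-class].
#' @return A [RadiusSkeleton-class] (empty for an empty mask).
#' @examples
#' m <- matrix(FALSE, 9, 25); m[4:6, 3:23] <- TRUE
#' sk <- buildSkeleton(rootMask(m))
#' sum(skeletonPixels(sk))
#' @export
buildSkeleton <- function(mask) {
  stopifnot(is(mask, "RootMask"))
  m <- pixels(mask)
  if (!any(m))
    return(new("RadiusSkeleton", radius = matrix(0, nrow(m), ncol(m)),
               pxPerMm = pxPerMm(mask)))
  dmap <- distanceTransform(mask)
  skel <- thinSkeleton(connectRidges(dmap, detectRidges(dmap)))
  new("RadiusSkeleton", radius = dmap * skel, pxPerMm = pxPerMm(mask))
}
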