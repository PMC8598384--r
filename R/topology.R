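# Topology of the thinned skeleton: tips (at most one skeleton neighbour),
# branch points (three or more) and the segments between them, plus the
# iterative pruning of invalid lateral roots. Pruning edits only the
# skeleton/topology, never the segmented mask.
#
# Internally the skeleton is converted once to node tables (pixel indices,
# coordinates, an n x 8 neighbour matrix) so that segment tracing is cheap
# even on large scans.

# Node tables for a logical skeleton matrix.
.skelGraph <- function(s) {
  nr <- nrow(s)
  idx <- which(s)
  n <- length(idx)
  nodeOf <- integer(length(s))
  nodeOf[idx] <- seq_len(n)
  idmat <- matrix(0L, nr, ncol(s))
  idmat[idx] <- seq_len(n)
  nbr <- matrix(0L, n, 8L)
  for (k in seq_len(8)) {
    sh <- shiftMat(idmat, .nbOffsets[k, 1], .nbOffsets[k, 2], 0L)
    nbr[, k] <- sh[idx]
  }
  list(idx = idx, n = n, nodeOf = nodeOf, nbr = nbr,
       deg = rowSums(nbr > 0L),
       row = ((idx - 1L) %% nr) + 1L,
       col = ((idx - 1L) %/% nr) + 1L)
}

.stepLenNodes <- function(g, a, b)
  sqrt((g$row[a] - g$row[b])^2 + (g$col[a] - g$col[b])^2)

#' Classify skeleton pixels and trace segments
#'
#' Labels every skeleton pixel as tip (`<=` 1 neighbour; an isolated pixel
#' is a degenerate tip), branch point (>= 3 neighbours) or segment pixel
#' (exactly 2), and traces every segment between two endpoints. Pure cycles
#' (components made only of degree-2 pixels) are returned as closed segments
#' with `end_types = c("LOOP", "LOOP")`.
#'
#' @param skel a [RadiusSkeleton-class] (thinned).
#' @return A [RootTopology-class].
#' @examples
#' m <- matrix(FALSE, 7, 11); m[4, 2:10] <- TRUE; m[1:3, 6] <- TRUE
#' topo <- classifyPixels(buildSkeleton(rootMask(m)))
#' countTips(topo); countBranchPoints(topo)
#' @export
classifyPixels <- function(skel) {
  stopifnot(is(skel, "RadiusSkeleton"))
  s <- skeletonPixels(skel)
  g <- .skelGraph(s)
  labels <- matrix(0L, nrow(s), ncol(s))
  nodeLab <- ifelse(g$deg <= 1L, TIP, ifelse(g$deg == 2L, SEGMENT, BRANCH))
  labels[g$idx] <- nodeLab
  segs <- .traceSegments(g, nodeLab)
  new("RootTopology", labels = labels, segments = segs)
}

.traceSegments <- function(g, nodeLab) {
  segs <- list()
  if (!g$n) return(segs)
  typeOf <- function(v) switch(nodeLab[v], "TIP", "BRANCH", "SEGMENT")
  # every segment is discovered once from each end; mark the directed
  # half-edge it starts with so the second traversal is skipped
  usedDir <- matrix(FALSE, g$n, 8L)
  endpoints <- which(nodeLab != SEGMENT)
  for (e in endpoints) {
    for (k in seq_len(8)) {
      nb <- g$nbr[e, k]
      if (nb == 0L || usedDir[e, k]) next
      path <- c(e, nb)
      prev <- e; cur <- nb
      while (nodeLab[cur] == SEGMENT) {
        nxt <- g$nbr[cur, ]
        nxt <- nxt[nxt > 0L & nxt != prev]
        if (!length(nxt)) break
        prev <- cur; cur <- nxt[1]
        path <- c(path, cur)
      }
      usedDir[e, k] <- TRUE
      kback <- which(g$nbr[cur, ] == prev)
      if (length(kback)) usedDir[cur, kback[1]] <- TRUE
      segs[[length(segs) + 1L]] <- .segmentRecordNodes(g, path,
        c(typeOf(e), typeOf(cur)))
    }
  }
  # pure cycles: degree-2 pixels not visited by any traced segment
  inSeg <- logical(g$n)
  for (sg in segs) inSeg[sg$nodes] <- TRUE
  loops <- which(nodeLab == SEGMENT & !inSeg)
  while (length(loops)) {
    start <- loops[1]
    path <- start
    prev <- start
    cur <- g$nbr[start, ][g$nbr[start, ] > 0L][1]
    while (cur != start) {
      path <- c(path, cur)
      nxt <- g$nbr[cur, ]
      nxt <- nxt[nxt > 0L & nxt != prev]
      prev <- cur
      cur <- nxt[1]
    }
    segs[[length(segs) + 1L]] <- .segmentRecordNodes(g, c(path, start),
                                                     c("LOOP", "LOOP"))
    loops <- setdiff(loops, path)
  }
  segs
}

.segmentRecordNodes <- function(g, path, endTypes) {
  len <- if (length(path) > 1L)
    sum(.stepLenNodes(g, path[-length(path)], path[-1L])) else 0
  list(path = cbind(g$row[path], g$col[path]), nodes = path,
       length_px = len, end_types = endTypes)
}

#' Prune invalid lateral roots
#'
#' An invalid lateral created by boundary roughness is no longer than the
#' radius of its parent root. Every branch-to-tip segment whose path length
#' is `<=` the branch pixel's radius plus `thresholdPx` is deleted (tip and
#' interior pixels; the branch pixel stays). Deletion is iterative - removing
#' a spur can merge segments and expose new prunable spurs - and runs until
#' no deletable segment remains. Candidates are processed in ascending
#' `length - radius` order (ties by branch row, then column); a candidate
#' invalidated by an earlier deletion in the same pass (its branch or tip
#' end no longer qualifies) is skipped and reconsidered on the next pass.
#' Segments joining two branch points and free tip-to-tip components are
#' never deleted; the segmented mask is never altered.
#'
#' @param skel a [RadiusSkeleton-class].
#' @param topo the matching [RootTopology-class] (from [classifyPixels()]).
#' @param thresholdPx non-negative pixel margin added to the branch radius.
#' @return A list with the pruned `skeleton` and its recomputed `topology`.
#' @export
pruneSkeleton <- function(skel, topo, thresholdPx) {
  stopifnot(is(skel, "RadiusSkeleton"), is(topo, "RootTopology"))
  if (thresholdPx < 0) stop("thresholdPx must be >= 0")
  rad <- radiusMap(skel)
  nr <- nrow(rad)
  repeat {
    segs <- rootSegments(topo)
    cand <- list()
    for (sg in segs) {
      if (!setequal(sg$end_types, c("TIP", "BRANCH"))) next
      bEnd <- if (sg$end_types[1] == "BRANCH") 1L else nrow(sg$path)
      bpix <- sg$path[bEnd, ]
      r <- rad[bpix[1], bpix[2]]
      if (sg$length_px <= r + thresholdPx)
        cand[[length(cand) + 1L]] <- list(seg = sg, score = sg$length_px - r,
                                          branch = bpix, branchEnd = bEnd)
    }
    if (!length(cand)) break
    ord <- order(vapply(cand, `[[`, numeric(1), "score"),
                 vapply(cand, function(x) x$branch[1], numeric(1)),
                 vapply(cand, function(x) x$branch[2], numeric(1)))
    s <- rad > 0
    # deletions are applied in order; the pass aborts at the first
    # candidate whose surroundings were modified by an earlier deletion,
    # so the realised prefix is identical to deleting one segment at a
    # time with full reclassification in between
    dirty <- matrix(FALSE, nr, ncol(s))
    markDirty <- function(px) {
      dirty[px] <<- TRUE
      for (k in seq_len(8)) {
        rr <- px[, 1] + .nbOffsets[k, 1]; cc <- px[, 2] + .nbOffsets[k, 2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(s)
        dirty[cbind(rr[ok], cc[ok])] <<- TRUE
      }
    }
    deletedAny <- FALSE
    for (k in ord) {
      sg <- cand[[k]]$seg
      bEnd <- cand[[k]]$branchEnd
      pth <- sg$path
      if (any(dirty[pth])) break
      drop <- pth[-bEnd, , drop = FALSE]
      before <- s
      s[drop] <- FALSE
      nbSeeds <- (drop[, 2] - 1L) * nr + drop[, 1]
      nbSeeds <- unique(c(nbSeeds,
                          (pth[bEnd, 2] - 1L) * nr + pth[bEnd, 1]))
      seedNbrs <- unlist(lapply(nbSeeds, function(i) {
        r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
        rr <- r + .nbOffsets[, 1]; cc <- c + .nbOffsets[, 2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(s)
        (cc[ok] - 1L) * nr + rr[ok]
      }))
      s <- .collapseCorners(s, cand = unique(c(nbSeeds, seedNbrs)))
      removed <- which(before & !s, arr.ind = TRUE)
      markDirty(removed)
      deletedAny <- TRUE
      # if the branch pixel dropped below three neighbours, its remaining
      # segments merge into new candidates: stop and reclassify
      br <- pth[bEnd, ]
      rr <- br[1] + .nbOffsets[, 1]; cc <- br[2] + .nbOffsets[, 2]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= ncol(s)
      if (!s[br[1], br[2]] || sum(s[cbind(rr[ok], cc[ok])]) < 3L) break
    }
    if (!deletedAny) break
    rad[!s] <- 0
    skel <- new("RadiusSkeleton", radius = rad, pxPerMm = pxPerMm(skel))
    topo <- classifyPixels(skel)
  }
  list(skeleton = skel, topology = topo)
}

# Alternate pruning with false-loop suppression until stable: pruning
# thins the junction meshes that block loop-breaking, and broken loops
# expose new prunable spurs.
.refineSkeleton <- function(skel, topo, mask, thresholdPx) {
  repeat {
    pruned <- pruneSkeleton(skel, topo, thresholdPx)
    skel <- pruned$skeleton
    topo <- pruned$topology
    rad <- radiusMap(skel)
    s2 <- .suppressFalseLoops(rad > 0, pixels(mask), rad)
    if (identical(s2, rad > 0)) return(pruned)
    rad[!s2] <- 0
    skel <- new("RadiusSkeleton", radius = rad, pxPerMm = pxPerMm(skel))
    topo <- classifyPixels(skel)
  }
}

#' Count root tips
#'
#' Tips are skeleton pixels with at most one neighbouring skeletal pixel.
#'
#' @param topo a [RootTopology-class].
#' @return Integer count.
#' @export
countTips <- function(topo) sum(topologyLabels(topo) == TIP)

#' Count branch points
#'
#' Branch points are skeleton pixels with at least three neighbouring
#' skeletal pixels.
#'
#' @param topo a [RootTopology-class].
#' @return Integer count.
#' @export
countBranchPoints <- function(topo) sum(topologyLabels(topo) == BRANCH)
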