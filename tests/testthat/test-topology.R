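# Hand-built skeletons (radius matrices) keep these tests independent of
# the skeletonization stage. Junctions use diagonal arms: under
# 8-connectivity a straight arm leaving a straight path orthogonally makes
# every pixel around the junction a branch point, whereas X/Y-shaped
# junctions have exactly one.

pathSkeleton <- function() {       # straight 10-px horizontal path
  rc <- cbind(4, 3:12)
  skeletonFromPixels(rc, rep(1, 10), c(8, 16))
}

ySkeleton <- function() {          # three diagonal/vertical arms, one junction
  rc <- rbind(c(8, 8),
              cbind(7:5, 9:11),    # NE arm
              cbind(7:5, 7:5),     # NW arm
              cbind(9:11, 8))      # S arm
  skeletonFromPixels(rc, rep(1, nrow(rc)), c(13, 13))
}

xSkeleton <- function() {          # four diagonal arms, one 4-neighbour hub
  rc <- rbind(c(8, 8),
              cbind(7:4, 9:12), cbind(7:4, 7:4),
              cbind(9:12, 9:12), cbind(9:12, 7:4))
  skeletonFromPixels(rc, rep(1, nrow(rc)), c(15, 15))
}

diamondRing <- function() {        # pure cycle of diagonal steps
  pts <- as.matrix(expand.grid(r = 1:13, c = 1:13))
  rc <- pts[abs(pts[, 1] - 7) + abs(pts[, 2] - 7) == 3, , drop = FALSE]
  skeletonFromPixels(rc, rep(1, nrow(rc)), c(13, 13))
}

# diagonal main path with an anti-diagonal spur of `len` steps at (10, 10)
spurSkeleton <- function(len, mainRadius = 3) {
  main <- cbind(2:20, 2:20)
  spur <- cbind(10 - seq_len(len), 10 + seq_len(len))
  rc <- rbind(main, spur)
  radii <- c(rep(mainRadius, nrow(main)), rep(1, len))
  skeletonFromPixels(rc, radii, c(22, 22 + len))
}

test_that("pixel classification matches neighbour-count semantics", {
  topo <- classifyPixels(pathSkeleton())
  expect_equal(countTips(topo), 2L)
  expect_equal(countBranchPoints(topo), 0L)
  expect_equal(length(rootSegments(topo)), 1L)
  expect_equal(rootSegments(topo)[[1]]$length_px, 9)

  yy <- classifyPixels(ySkeleton())
  expect_equal(countTips(yy), 3L)
  expect_equal(countBranchPoints(yy), 1L)
  expect_equal(length(rootSegments(yy)), 3L)

  xx <- classifyPixels(xSkeleton())
  expect_equal(countTips(xx), 4L)
  expect_equal(countBranchPoints(xx), 1L)   # the hub has 4 neighbours
  expect_equal(length(rootSegments(xx)), 4L)
})

test_that("an isolated pixel counts as a degenerate tip", {
  sk <- skeletonFromPixels(cbind(3, 3), 1, c(6, 6))
  topo <- classifyPixels(sk)
  expect_equal(countTips(topo), 1L)
  expect_equal(totalLength(sk)[["px"]], 0)
})

test_that("pure cycles are traced as loop segments", {
  topo <- classifyPixels(diamondRing())
  expect_equal(countTips(topo), 0L)
  expect_equal(countBranchPoints(topo), 0L)
  segs <- rootSegments(topo)
  expect_equal(length(segs), 1L)
  expect_equal(segs[[1]]$end_types, c("LOOP", "LOOP"))
})

test_that("pruning follows the radius-plus-margin rule", {
  # branch radius 3, threshold 5: spurs up to length 8 px go
  s5 <- spurSkeleton(5)    # 5 * sqrt(2) = 7.07 <= 8: removed
  pr5 <- pruneSkeleton(s5, classifyPixels(s5), 5)
  expect_equal(countTips(pr5$topology), 2L)
  expect_equal(countBranchPoints(pr5$topology), 0L)

  s7 <- spurSkeleton(7)    # 9.90 > 8: retained
  pr7 <- pruneSkeleton(s7, classifyPixels(s7), 5)
  expect_equal(countTips(pr7$topology), 3L)
  expect_equal(countBranchPoints(pr7$topology), 1L)
})

test_that("segments joining two branch points are never pruned", {
  # two Y junctions joined by a short crossbar; arms are prunable
  rc <- rbind(c(8, 8), cbind(7:5, 7:5), cbind(9:11, 7:5),
              cbind(8, 9:15),
              c(8, 16), cbind(7:5, 17:19), cbind(9:11, 17:19))
  sk <- skeletonFromPixels(rc, rep(10, nrow(rc)), c(14, 24))
  pr <- pruneSkeleton(sk, classifyPixels(sk), 50)
  lab <- topologyLabels(pr$topology)
  expect_true(all(lab[cbind(8, 8:16)] > 0))   # crossbar + old junctions
  expect_equal(countTips(pr$topology), 2L)
})

test_that("tip-to-tip components survive pruning and the mask is untouched", {
  sk <- pathSkeleton()
  pr <- pruneSkeleton(sk, classifyPixels(sk), 100)
  expect_identical(radiusMap(pr$skeleton), radiusMap(sk))
})

test_that("cascading spur removal matches the one-deletion-at-a-time oracle", {
  # herringbone: several spurs along the main axis
  rc <- cbind(2:26, 2:26)
  for (k in c(8, 14, 20))
    rc <- rbind(rc, cbind(k - seq_len(3), k + seq_len(3)))
  sk <- skeletonFromPixels(rc, rep(2, nrow(rc)), c(28, 32))
  pr <- pruneSkeleton(sk, classifyPixels(sk), 3)
  expect_identical(skeletonPixels(pr$skeleton), prunedByOracle(sk, 3))
  expect_equal(countTips(pr$topology), 2L)

  set.seed(71)
  for (i in 1:40) {
    rs <- randomSkeleton(28, 28)
    if (!any(skeletonPixels(rs))) next
    thr <- sample(0:6, 1)
    mine <- pruneSkeleton(rs, classifyPixels(rs), thr)
    expect_identical(skeletonPixels(mine$skeleton), prunedByOracle(rs, thr))
  }
})

test_that("pruning is idempotent and only ever shrinks the skeleton", {
  set.seed(72)
  for (i in 1:15) {
    rs <- randomSkeleton(26, 26)
    before <- totalLength(rs)[["px"]]
    topo <- classifyPixels(rs)
    tipsBefore <- countTips(topo)
    pr <- pruneSkeleton(rs, topo, 4)
    expect_lte(totalLength(pr$skeleton)[["px"]], before)
    expect_lte(countTips(pr$topology), max(tipsBefore, 1L))
    again <- pruneSkeleton(pr$skeleton, pr$topology, 4)
    expect_identical(radiusMap(again$skeleton), radiusMap(pr$skeleton))
  }
})

test_that("tip and branch counters read the topology labels", {
  expect_equal(countTips(classifyPixels(ySkeleton())), 3L)
  expect_equal(countBranchPoints(classifyPixels(ySkeleton())), 1L)
  emptyTopo <- classifyPixels(skeletonFromPixels(cbind(1, 1)[0, , drop = FALSE],
                                                 numeric(), c(5, 5)))
  expect_equal(countTips(emptyTopo), 0L)
  expect_equal(countBranchPoints(emptyTopo), 0L)
  two <- rbind(cbind(2, 2:8), cbind(6, 2:8))
  topo2 <- classifyPixels(skeletonFromPixels(two, rep(1, nrow(two)), c(8, 10)))
  expect_equal(countTips(topo2), 4L)
  expect_equal(countBranchPoints(topo2), 0L)
})
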