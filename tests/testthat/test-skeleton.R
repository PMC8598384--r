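test_that("distance transform is exact against brute force", {
  empty <- rootMask(matrix(FALSE, 6, 6))
  expect_true(all(distanceTransform(empty) == 0))

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(distanceTransform(rootMask(one))[3, 3], 1)

  bar <- matrix(FALSE, 5, 20); bar[2:4, ] <- TRUE
  d <- distanceTransform(rootMask(bar))
  bf <- bruteForceEDT(bar)
  expect_equal(d, bf)
  expect_equal(unique(d[3, 5:15]), 2)   # centre row of a 3-px bar
  expect_equal(unique(d[2, 5:15]), 1)

  set.seed(21)
  for (i in 1:25) {
    m <- matrix(stats::runif(35 * 35) < stats::runif(1, 0.2, 0.8), 35, 35)
    m[1, 1] <- FALSE
    expect_equal(distanceTransform(rootMask(m)), bruteForceEDT(m))
  }
})

test_that("ridge detection finds centrelines and nothing on flats", {
  line <- matrix(FALSE, 5, 15); line[3, 2:14] <- TRUE
  r <- detectRidges(distanceTransform(rootMask(line)))
  expect_true(all(r[3, 2:14]))
  expect_equal(sum(r), 13)

  bar <- matrix(FALSE, 7, 20); bar[3:5, ] <- TRUE
  rb <- detectRidges(distanceTransform(rootMask(bar)))
  expect_true(all(rb[4, 5:15]))
  expect_false(any(rb[3, 5:15]))
  expect_false(any(rb[5, 5:15]))

  expect_equal(sum(detectRidges(matrix(0, 8, 8))), 0)
})

test_that("ridge connection yields one skeleton component per mask component", {
  bar <- matrix(FALSE, 7, 20); bar[3:5, ] <- TRUE
  d <- distanceTransform(rootMask(bar))
  r <- detectRidges(d)
  expect_identical(connectRidges(d, r), connectRidges(d, connectRidges(d, r)))

  # lateral meeting a wide parent stays a single skeleton component
  tm <- matrix(FALSE, 30, 40)
  tm[5:11, 3:38] <- TRUE
  tm[12:25, 19:21] <- TRUE
  dt <- distanceTransform(rootMask(tm))
  expect_equal(nComponents(connectRidges(dt, detectRidges(dt))), 1L)

  two <- matrix(FALSE, 20, 20)
  two[3:6, 3:6] <- TRUE; two[13:16, 13:16] <- TRUE
  d2 <- distanceTransform(rootMask(two))
  expect_equal(nComponents(connectRidges(d2, detectRidges(d2))), 2L)

  # random blobs routinely produce detached ridge fragments; connection
  # must always restore exactly one skeleton component per mask component
  set.seed(51)
  detached <- 0L
  for (i in 1:25) {
    m <- randomMask(30, 30)
    if (!any(m)) next
    dm <- distanceTransform(rootMask(m))
    r <- detectRidges(dm)
    if (nComponents(r) > nComponents(m)) detached <- detached + 1L
    expect_equal(nComponents(connectRidges(dm, r)), nComponents(m))
  }
  expect_gt(detached, 0L)
})

test_that("thinning reaches one-pixel width and preserves topology", {
  line <- matrix(FALSE, 5, 15); line[3, 2:14] <- TRUE
  expect_identical(thinSkeleton(line), line)

  band <- matrix(FALSE, 8, 30); band[4:5, 3:28] <- TRUE
  tb <- thinSkeleton(band)
  blocks <- tb & rootquant:::shiftMat(tb, 0, 1, FALSE) &
    rootquant:::shiftMat(tb, 1, 0, FALSE) &
    rootquant:::shiftMat(tb, 1, 1, FALSE)
  expect_false(any(blocks))
  expect_equal(nComponents(tb), 1L)
  span <- range(which(colSums(tb) > 0))
  expect_lte(span[1], 5)                      # ends eroded by at most 2 px
  expect_gte(span[2], 26)

  # a 2-px-wide closed ring thins to a 1-px loop (cycle rank still 1)
  ring <- matrix(FALSE, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    rad <- sqrt((i - 10.5)^2 + (j - 10.5)^2)
    if (rad >= 5 && rad <= 7) ring[i, j] <- TRUE
  }
  tr <- thinSkeleton(ring)
  expect_equal(nComponents(tr), 1L)
  expect_equal(cycleRankOracle(tr), 1L)

  expect_identical(thinSkeleton(tb), tb)     # idempotent
  set.seed(31)
  for (i in 1:20) {
    m <- randomMask(25, 25)
    th <- thinSkeleton(m)
    expect_equal(nComponents(th), nComponents(m))
    expect_identical(thinSkeleton(th), th)
  }
})

test_that("buildSkeleton composes the stages with radii from the distance map", {
  bar <- matrix(FALSE, 9, 27); bar[4:6, 4:24] <- TRUE   # 21 x 3 bar
  sk <- buildSkeleton(rootMask(bar))
  s <- skeletonPixels(sk)
  expect_equal(nComponents(s), 1L)
  expect_true(all(radiusMap(sk)[s] == bruteForceEDT(bar)[s]))
  expect_equal(sort(unique(radiusMap(sk)[s & col(s) %in% 8:20])), 2)

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  sk1 <- buildSkeleton(rootMask(one))
  expect_equal(sum(skeletonPixels(sk1)), 1L)
  expect_equal(max(radiusMap(sk1)), 1)

  emptySk <- buildSkeleton(rootMask(matrix(FALSE, 4, 4)))
  expect_equal(sum(skeletonPixels(emptySk)), 0L)

  # plus-sign: four arms meeting centrally
  p <- matrix(FALSE, 31, 31)
  p[14:18, 4:28] <- TRUE; p[4:28, 14:18] <- TRUE
  skp <- buildSkeleton(rootMask(p))
  pr <- pruneSkeleton(skp, classifyPixels(skp), 5)
  expect_equal(countTips(pr$topology), 4L)
  expect_gte(countBranchPoints(pr$topology), 1L)
})

test_that("skeleton component count matches the mask on random blobs", {
  set.seed(41)
  for (i in 1:25) {
    m <- randomMask(30, 30)
    if (!any(m)) next
    s <- skeletonPixels(buildSkeleton(rootMask(m)))
    expect_equal(nComponents(s), nComponents(m))
  }
})

test_that("straight odd-width bars recover the centre-row radius", {
  for (w in c(3, 5, 7, 9)) {
    m <- matrix(FALSE, w + 8, 60)
    m[5:(4 + w), 5:55] <- TRUE
    sk <- buildSkeleton(rootMask(m))
    topo <- classifyPixels(sk)
    sk <- pruneSkeleton(sk, topo, 5)$skeleton
    s <- skeletonPixels(sk)
    centreVal <- bruteForceEDT(m)[5 + (w - 1) %/% 2, 30]
    expect_equal(stats::median(radiusMap(sk)[s]), centreVal)
  }
})
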