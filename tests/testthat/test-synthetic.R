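test_that("wire scenes carry analytic truth from the rendered geometry", {
  # 1 mm x 50 mm wire at 600 DPI renders 24 px wide
  s <- 600 / 25.4
  sc <- renderWires(list(wireSpec(1, 50, position = c(40.5, 600))),
                    pxPerMm = s)
  expect_equal(sc$wires$width_px, 24)
  expect_equal(sc$truth$total_length_mm, round(50 * s) / s, tolerance = 1e-9)
  D <- 24 / s
  expect_equal(sc$truth$weighted_avg_diameter_mm, D)
  expect_equal(sc$truth$volume_mm3,
               pi * (D / 2)^2 * sc$truth$total_length_mm, tolerance = 1e-9)
  expect_equal(sc$truth$surface_area_mm2,
               pi * D * sc$truth$total_length_mm, tolerance = 1e-9)

  empty <- renderWires(list(), pxPerMm = 10, canvasDim = c(20, 20))
  expect_equal(empty$truth$total_length_mm, 0)
  expect_equal(empty$truth$object_count, 0)
  expect_true(all(pixels(empty$image) == 255))

  two <- renderWires(list(wireSpec(0.2, 100, position = c(10.5, 600)),
                          wireSpec(2, 100, position = c(40.5, 600))),
                     pxPerMm = 10)
  expect_equal(two$truth$volume_mm3, sum(two$wires$volume_mm3))
  expect_equal(two$truth$object_count, 2)

  expect_error(renderWires(list(wireSpec(1, 30, position = c(20.5, 160)),
                                wireSpec(1, 30, position = c(22.5, 160))),
                           pxPerMm = 10), "overlap")
})

test_that("rendered stroke widths equal the rounded physical width", {
  s <- 10
  for (d in c(0.1, 0.25, 0.5, 1, 1.55, 3)) {
    w <- max(1, round(d * s))
    sc <- renderWires(list(wireSpec(d, 20, position = c(20 + (w - 1) / 2,
                                                        110))), pxPerMm = s)
    m <- pixels(sc$image) < 128
    expect_equal(sum(m[, 60]), w)     # cross-section mid-wire
  }
})

test_that("arc wires recover curved path length", {
  # gentle curvature leaves long boundary staircase runs whose medial
  # spurs exceed the 5 px pruning margin, so curved-path length carries a
  # few percent of spur length; the tolerance reflects that
  s <- 10
  sc <- renderWires(list(wireSpec(0.5, 40, position = c(60, 220),
                                  shape = "arc", arc_angle_deg = 120)),
                    pxPerMm = s)
  cfg <- analysisConfig(thresholdLevel = 191, pruningEnabled = TRUE,
                        pruningThresholdPx = 5, pxPerMm = s)
  rec <- extractFeatures(sc$image, cfg)
  expect_equal(rec$total_length_mm, sc$truth$total_length_mm,
               tolerance = 0.08)
  expect_equal(rec$tip_count, 2L)
})

test_that("branched phantoms know their topology truth", {
  mainOnly <- renderBranchedRoot(300, 11, laterals = list())
  cfg <- analysisConfig(thresholdLevel = 191, pruningEnabled = TRUE,
                        pruningThresholdPx = 5)
  rec0 <- extractFeatures(mainOnly$image, cfg)
  expect_equal(rec0$tip_count, 2L)
  expect_equal(rec0$branch_point_count, 0L)

  br <- renderBranchedRoot(500, 15,
                           laterals = list(c(120, 160, 5), c(240, 160, 5),
                                           c(360, 160, 5)))
  rec <- extractFeatures(br$image, cfg)
  expect_equal(rec$tip_count, br$truth$tip_count)
  expect_equal(rec$branch_point_count, br$truth$branch_point_count)
  truthLen <- br$truth$main_length_px + sum(br$truth$lateral_lengths_px)
  expect_equal(rec$total_length_px, truthLen, tolerance = 0.02)

  expect_error(renderBranchedRoot(300, 11,
                                  laterals = list(c(100, 50, 5),
                                                  c(103, 50, 5))),
               "overlap")
})

test_that("a diameter bin edge between orders splits the length truthfully", {
  br <- renderBranchedRoot(800, 15,
                           laterals = list(c(150, 300, 5), c(400, 300, 5),
                                           c(650, 300, 5)))
  cfg <- analysisConfig(thresholdLevel = 191, pruningEnabled = TRUE,
                        pruningThresholdPx = 5, diameterBinEdges = 10)
  rec <- extractFeatures(br$image, cfg)
  truthLat <- sum(br$truth$lateral_lengths_px)
  truthMain <- br$truth$main_length_px
  expect_equal(rec$Length.Range.1, truthLat, tolerance = 0.02)
  expect_equal(rec$Length.Range.2, truthMain, tolerance = 0.02)
})

test_that("seeded corruption is reproducible and reversible by filtering", {
  sc <- renderWires(list(wireSpec(1.2, 40, position = c(25.5, 210))),
                    pxPerMm = 10)
  c1 <- corruptImage(sc$image, speckleCount = 6, speckleSizePx = 4,
                     holeCount = 4, holeSizePx = 4, seed = 99)
  c2 <- corruptImage(sc$image, speckleCount = 6, speckleSizePx = 4,
                     holeCount = 4, holeSizePx = 4, seed = 99)
  expect_identical(pixels(c1), pixels(c2))
  expect_false(identical(pixels(c1), pixels(sc$image)))

  clean <- thresholdImage(sc$image, 191)
  restored <- fillHoles(filterBackgroundNoise(thresholdImage(c1, 191), 5), 5)
  expect_identical(pixels(restored), pixels(clean))

  # and the final features agree once filtering is on
  cfg <- analysisConfig(thresholdLevel = 191, filterBackground = TRUE,
                        maxComponentSize = 5, fillHoles = TRUE,
                        maxHoleSize = 5, pruningEnabled = TRUE,
                        pruningThresholdPx = 5)
  recClean <- extractFeatures(sc$image, cfg)
  recCorrupt <- extractFeatures(c1, cfg)
  drop <- "computation_time_s"
  expect_equal(recCorrupt[setdiff(names(recCorrupt), drop)],
               recClean[setdiff(names(recClean), drop)], tolerance = 1e-9)
})

test_that("validation scenes span the gauge ladder deterministically", {
  s1 <- wireValidationScenes(nScenes = 2, seed = 5)
  s2 <- wireValidationScenes(nScenes = 2, seed = 5)
  expect_identical(pixels(s1[[1]]$image), pixels(s2[[1]]$image))
  expect_equal(s1[[1]]$truth$object_count, 6)
  expect_equal(range(s1[[1]]$wires$width_px), c(2, 61))
  expect_false(identical(pixels(s1[[1]]$image), pixels(s1[[2]]$image)))
})
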