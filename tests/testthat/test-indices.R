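test_that("arch indices follow their defining ratios", {
  expect_equal(staheliIndex(2.5, 5), 0.5)
  expect_equal(staheliIndex(0, 5), 0)
  expect_equal(staheliIndex(4, 4), 1)
  expect_error(staheliIndex(2, 0), "degenerate hindfoot")
  expect_equal(chippauxSmirak(2.5, 10), 25)
  expect_equal(chippauxSmirak(0, 10), 0)
  expect_equal(chippauxSmirak(7, 7), 100)
  expect_error(chippauxSmirak(2, 0), "degenerate forefoot")
  # unit independence: px and cm inputs agree
  expect_equal(staheliIndex(80, 160), staheliIndex(2, 4))
  expect_equal(chippauxSmirak(80, 160), chippauxSmirak(2, 4))
})

test_that("the arch angle matches the law of cosines at the forefoot vertex", {
  expect_equal(clarkeAngle(1, 1, 1), 60)
  # t1 = (0,0), s1 = (4,3), f1 = (10,0): S = 5, T = 10, F = sqrt(45)
  expect_equal(clarkeAngle(5, 10, sqrt(45)), 36.8699, tolerance = 1e-4)
  expect_equal(clarkeAngle(5, 10, sqrt(45), "as_printed"), 26.5651,
               tolerance = 1e-4)
  expect_error(clarkeAngle(1, 10, 1), "degenerate triangle")
  # s1 collinear beyond f1: zero angle at the shared vertex, flagged
  expect_warning(a <- clarkeAngle(5, 2, 3), "collinear")
  expect_equal(a, 0)
  # oracle equivalence: dot-product angle at t1 for random triangles
  set.seed(99)
  for (i in 1:1000) {
    t1 <- stats::runif(2, 0, 100)
    s1 <- stats::runif(2, 0, 100)
    f1 <- stats::runif(2, 0, 100)
    S <- sqrt(sum((s1 - t1)^2)); T <- sqrt(sum((f1 - t1)^2))
    F <- sqrt(sum((s1 - f1)^2))
    if (min(S, T, F) < 1e-3) next
    v1 <- s1 - t1; v2 <- f1 - t1
    oracle <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    expect_equal(clarkeAngle(S, T, F), oracle, tolerance = 1e-9)
  }
})

test_that("five-group classification matches the published ranges", {
  expect_equal(classifyValue(0.5, "staheli"), 3L)
  expect_equal(classifyValue(25, "csi"), 2L)       # 0.25 on fraction scale
  expect_equal(classifyValue(55, "clarke"), 1L)
  # boundary conventions: ascending lower-inclusive; descending boundary
  # joins the higher-arch group
  expect_equal(classifyValue(c(0.29, 0.3, 0.4, 0.7, 0.8, 0.81), "staheli"),
               c(1L, 2L, 3L, 4L, 5L, 5L))
  expect_equal(classifyValue(c(21, 22, 30, 50, 70, 71), "csi"),
               c(1L, 2L, 3L, 4L, 5L, 5L))
  expect_equal(classifyValue(c(51, 50, 38, 26, 15, 14), "clarke"),
               c(1L, 1L, 2L, 3L, 4L, 5L))
  cls <- classify(IndexSet(0.5, 25, 55))
  expect_equal(unname(groups(cls)), c(3L, 2L, 1L))
  expect_equal(unname(cls@labels),
               c("Normal", "Cavus-Normal", "Cavus"))
})

test_that("every real value lands in exactly one classification group", {
  set.seed(31)
  xs <- c(stats::runif(300, -1, 2), stats::runif(300, 0, 120),
          c(0.3, 0.4, 0.7, 0.8, 0.22, 0.5, 15, 26, 38, 50))
  for (index in c("staheli", "csi", "clarke")) {
    g <- classifyValue(xs, index)
    expect_true(all(g %in% 1:5))
    expect_length(g, length(xs))
  }
  # monotone: larger Staheli/CSI values never map to a smaller group,
  # larger arch angles never to a larger group
  xs <- sort(stats::runif(500, 0, 1.2))
  expect_true(all(diff(classifyValue(xs, "staheli")) >= 0))
  expect_true(all(diff(classifyValue(100 * xs, "csi")) >= 0))
  ys <- sort(stats::runif(500, 0, 90))
  expect_true(all(diff(classifyValue(ys, "clarke")) <= 0))
})

test_that("index computation is unit-invariant through an index set", {
  sf <- generateFootprint(FootShapeParams(seed = 5))
  foot <- detectFeetAndSides(extractFootprints(sf@trueMask,
                                               expectedFeet = "1"))[[1]]
  sc <- new("CalibrationScale", pixelsPerCm = 40, squareAreaPx = 1600L)
  meas <- measureSegments(foot, sc)
  ind <- computeIndices(meas)
  lcm <- segmentLengths(meas, "cm")
  expect_equal(staheli(ind), lcm[["Q"]] / lcm[["R"]], tolerance = 1e-9)
  expect_equal(chippauxSmirakPct(ind), 100 * lcm[["Q"]] / lcm[["P"]],
               tolerance = 1e-9)
  expect_equal(clarkeDeg(ind),
               clarkeAngle(lcm[["S"]], lcm[["T"]], lcm[["F"]]),
               tolerance = 1e-9)
})

test_that("the pipeline classifies flat and cavus renders into opposite groups", {
  flat <- generateFootprint(FootShapeParams(archDepthPx = 6, seed = 41))
  resF <- analyzeFootprint(flat@image)[[1]]
  expect_true(groups(classification(resF))["csi"] %in% c(4L, 5L))
  cavus <- generateFootprint(FootShapeParams(archDepthPx = 135, seed = 42))
  resC <- analyzeFootprint(cavus@image)[[1]]
  expect_true(groups(classification(resC))["csi"] %in% c(1L, 2L))
})

test_that("stage failures are reported with the failing stage named", {
  blank <- flatImage(100, 80, c(245, 245, 245))
  expect_error(analyzeFootprint(blank), "\\[segmentation\\]")
  sf <- generateFootprint(FootShapeParams(seed = 8))
  noMarker <- sf@image
  noMarker[500:600, , ] <- 245  # paint the marker out
  expect_error(analyzeFootprint(noMarker), "\\[calibration\\]")
  expect_warning(res <- analyzeFootprint(noMarker,
                                         allowUncalibrated = TRUE),
                 "pixel units")
  expect_null(calibration(res[[1]]))
  expect_true(is.na(segments(res[[1]])$Q@lengthCm))
})

test_that("analysis reports are deterministic and carry the config echo", {
  sf <- generateFootprint(FootShapeParams(seed = 23, noiseSd = 2))
  r1 <- analyzeFootprint(sf@image)
  r2 <- analyzeFootprint(sf@image)
  j1 <- footprintReport(r1)
  j2 <- footprintReport(r2)
  expect_identical(as.character(j1), as.character(j2))
  parsed <- jsonlite::fromJSON(as.character(j1), simplifyVector = FALSE)
  expect_equal(parsed$config$aThreshold, 122)
  expect_equal(parsed$feet[[1]]$side, "left")
  expect_equal(parsed$feet[[1]]$calibration$pixelsPerCm, 40)
})

test_that("two-foot images are analysed per foot with facing arches", {
  # seen from below, the subject's left foot appears on image-left and its
  # medial arch faces image-right, toward the other foot
  l <- generateFootprint(FootShapeParams(side = "left", seed = 61))
  r <- generateFootprint(FootShapeParams(side = "right", seed = 62))
  both <- array(0, dim = c(600, 642, 3))
  both[, 1:321, ] <- l@image
  both[, 322:642, ] <- r@image
  res <- analyzeFootprint(both, expectedFeet = "2")
  expect_length(res, 2)
  expect_equal(footSide(res[[1]]), "left")
  expect_equal(footSide(res[[2]]), "right")
})
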