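test_that("Euclidean distance follows the two-point formula", {
  expect_equal(euclideanDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclideanDistance(c(7, 7), c(7, 7)), 0)
  expect_equal(euclideanDistance(c(2, 1), c(5, 5)), 5)
  expect_equal(euclideanDistance(c(5, 5), c(2, 1)), 5)  # symmetry
})

test_that("zone partition splits bounding rows into thirds, remainder to hindfoot", {
  m <- matrix(0L, 120, 20); m[1:90, 5:15] <- 1L
  z <- partitionZones(m)
  expect_equal(z@forefoot, c(1L, 31L))
  expect_equal(z@midfoot, c(31L, 61L))
  expect_equal(z@hindfoot, c(61L, 91L))
  m2 <- matrix(0L, 40, 20); m2[11:21, 5:15] <- 1L  # 11 rows: 3 + 3 + 5
  z2 <- partitionZones(m2)
  expect_equal(diff(z2@forefoot), 3L)
  expect_equal(diff(z2@midfoot), 3L)
  expect_equal(diff(z2@hindfoot), 5L)
  m3 <- matrix(0L, 10, 10); m3[4:5, 2:8] <- 1L
  expect_error(partitionZones(m3), "too small")
})

test_that("width profile reports pixel-centre widths and omits empty rows", {
  m <- matrix(0L, 30, 30); m[1:30, 11:20] <- 1L
  foot <- asFootRegion(m)
  wp <- widthProfile(foot, "midfoot")
  expect_true(all(wp$widthPx == 9))
  expect_true(all(wp$outerCol == 11) && all(wp$innerCol == 20))
  # hourglass narrowing to 3 px at its waist
  hg <- matrix(0L, 30, 30)
  for (r in 1:30) {
    half <- 1 + min(7, abs(r - 15))
    hg[r, (15 - half):(15 + half)] <- 1L
  }
  hg[15, ] <- 0L; hg[15, 14:16] <- 1L
  wfoot <- asFootRegion(hg)
  wp2 <- widthProfile(wfoot, "midfoot")
  expect_equal(min(wp2$widthPx), 2)
  expect_equal(wp2$row[which.min(wp2$widthPx)], 15)
  empty <- matrix(0L, 30, 30); empty[1:10, 5:25] <- 1L
  # zones come from the bounding box, so an all-empty zone cannot arise from
  # partitioning; force one via a hand-built region
  zr <- new("FootRegion", mask = empty, side = "left",
            medialDirection = "image-right",
            zones = new("ZonePartition", forefoot = c(1L, 11L),
                        midfoot = c(11L, 21L), hindfoot = c(21L, 31L)))
  expect_error(widthProfile(zr, "midfoot"), "empty zone")
})

test_that("extreme-width scans match exhaustive brute-force scans", {
  set.seed(7)
  for (i in 1:25) {
    m <- randomBlobMask()
    foot <- asFootRegion(m)
    for (zone in c("forefoot", "midfoot", "hindfoot")) {
      z <- slot(foot@zones, zone)
      oracle <- bruteRowScan(m, z[1L], z[2L] - 1L, medialRight = TRUE)
      wp <- widthProfile(foot, zone)
      expect_equal(wp$row, unname(oracle[, "row"]))
      expect_equal(wp$widthPx, unname(oracle[, "width"]))
      expect_equal(wp$outerCol, unname(oracle[, "outer"]))
    }
    # Q equals the brute-force midfoot minimum
    z <- foot@zones@midfoot
    oracle <- bruteRowScan(m, z[1L], z[2L] - 1L, TRUE)
    expect_equal(findQ(foot)@lengthPx, min(oracle[, "width"]))
    z <- foot@zones@hindfoot
    oracle <- bruteRowScan(m, z[1L], z[2L] - 1L, TRUE)
    expect_equal(findR(foot)@lengthPx, max(oracle[, "width"]))
    z <- foot@zones@forefoot
    oracle <- bruteRowScan(m, z[1L], z[2L] - 1L, TRUE)
    expect_equal(findP(foot)@lengthPx, max(oracle[, "width"]))
  }
})

test_that("a rectangular foot has equal Q, R and P and aligned tangent points", {
  m <- matrix(0L, 90, 40); m[10:75, 12:28] <- 1L
  foot <- asFootRegion(m)
  q <- findQ(foot); r <- findR(foot); p <- findP(foot)
  expect_equal(q@lengthPx, 16)
  expect_equal(r@lengthPx, 16)
  expect_equal(p@lengthPx, 16)
  cp <- findClarkePoints(foot)
  expect_equal(cp$t1[2], cp$f1[2])  # tangent points on the same column
  # tie-breaking: extremal rows sit nearest each zone's centre row
  zc <- (foot@zones@midfoot[1L] + foot@zones@midfoot[2L] - 1) / 2
  expect_lte(abs(q@start[1L] - zc), 0.5)
})

test_that("side detection reads the medial arch concavity", {
  s <- generateFootprint(FootShapeParams(side = "left", seed = 21))
  masks <- extractFootprints(s@trueMask, expectedFeet = "1")
  foot <- detectFeetAndSides(masks)[[1]]
  expect_equal(footSide(foot), "left")
  expect_equal(foot@medialDirection, "image-right")
  # mirrored mask flips the side
  mir <- s@trueMask[, ncol(s@trueMask):1]
  footM <- detectFeetAndSides(list(mir))[[1]]
  expect_equal(footSide(footM), "right")
  # featureless rectangle: ambiguous
  rect <- matrix(0L, 80, 30); rect[10:70, 8:22] <- 1L
  expect_error(detectFeetAndSides(list(rect)), "side ambiguous")
  forced <- detectFeetAndSides(list(rect), forceSide = "left")[[1]]
  expect_equal(footSide(forced), "left")
})

test_that("measured segments assemble the S, T, F triangle with correct lengths", {
  # geometry chosen so t1 = (10, 10), s1 = (14, 13), f1 = (20, 10) after
  # measurement: verify via a hand-built region is brittle, so check the
  # arithmetic through LineSegment construction directly
  sc <- new("CalibrationScale", pixelsPerCm = 40, squareAreaPx = 1600L)
  s <- LineSegment(c(0, 0), c(4, 3), sc)
  expect_equal(s@lengthPx, 5)
  expect_equal(s@lengthCm, 0.125)
  t <- LineSegment(c(0, 0), c(10, 0))
  expect_equal(t@lengthPx, 10)
  expect_true(is.na(t@lengthCm))
  f <- LineSegment(c(10, 0), c(4, 3))
  expect_equal(f@lengthPx, sqrt(45))
  # a calibrated 80 px segment is 2 cm at 40 px/cm
  expect_equal(LineSegment(c(0, 0), c(0, 80), sc)@lengthCm, 2)
  # full assembly on a synthetic foot: invariants hold
  sf <- generateFootprint(FootShapeParams(seed = 3))
  foot <- detectFeetAndSides(extractFootprints(sf@trueMask,
                                               expectedFeet = "1"))[[1]]
  meas <- measureSegments(foot, sc)
  pts <- keyPoints(meas)
  segs <- segments(meas)
  expect_equal(unname(segs$S@start), unname(pts["t1", ]))
  expect_equal(unname(segs$S@end), unname(pts["s1", ]))
  expect_equal(unname(segs$T@end), unname(pts["f1", ]))
  expect_equal(unname(segs$F@start), unname(pts["f1", ]))
  expect_equal(segs$Q@lengthCm, segs$Q@lengthPx / 40)
})

test_that("measurements are mirror- and translation-invariant", {
  sf <- generateFootprint(FootShapeParams(seed = 13, archDepthPx = 70))
  m <- sf@trueMask
  foot <- detectFeetAndSides(extractFootprints(m, expectedFeet = "1"))[[1]]
  lens <- segmentLengths(measureSegments(foot))
  # mirror: lengths unchanged, side flips
  mir <- m[, ncol(m):1]
  footM <- detectFeetAndSides(extractFootprints(mir,
                                                expectedFeet = "1"))[[1]]
  lensM <- segmentLengths(measureSegments(footM))
  expect_equal(unname(lensM), unname(lens), tolerance = 1e-12)
  expect_equal(footSide(footM), "right")
  # translation: pad 15 rows / 10 cols
  sh <- matrix(0L, nrow(m) + 15L, ncol(m) + 10L)
  sh[15L + seq_len(nrow(m)), 10L + seq_len(ncol(m))] <- m
  footT <- detectFeetAndSides(extractFootprints(sh,
                                                expectedFeet = "1"))[[1]]
  measT <- measureSegments(footT)
  meas0 <- measureSegments(foot)
  expect_equal(unname(segmentLengths(measT)), unname(lens),
               tolerance = 1e-12)
  expect_equal(unname(keyPoints(measT)),
               unname(keyPoints(meas0) + rep(c(15, 10), each = 9)))
})

test_that("integer upsampling scales all segment lengths proportionally", {
  sf <- generateFootprint(FootShapeParams(seed = 17))
  m <- sf@trueMask
  big <- m[rep(seq_len(nrow(m)), each = 2L), rep(seq_len(ncol(m)), each = 2L)]
  foot1 <- detectFeetAndSides(extractFootprints(m, expectedFeet = "1"))[[1]]
  foot2 <- detectFeetAndSides(extractFootprints(big,
                                                expectedFeet = "1"))[[1]]
  l1 <- segmentLengths(measureSegments(foot1))
  l2 <- segmentLengths(measureSegments(foot2))
  expect_true(all(abs(l2 - 2 * l1) <= 4))  # +-2 px at the doubled scale
})

test_that("annotation draws the measured lines into the image", {
  sf <- generateFootprint(FootShapeParams(seed = 9))
  res <- analyzeFootprint(sf@image)[[1]]
  ann <- annotateFootprint(sf@image, measurements(res))
  expect_equal(dim(ann), dim(sf@image))
  expect_false(identical(ann, sf@image))
  path <- tempfile(fileext = ".png")
  annotateFootprint(sf@image, measurements(res), path)
  expect_true(file.exists(path))
  back <- readFootprintImage(path)
  expect_equal(dim(back), dim(sf@image))
})
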