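test_that("CIELAB thresholding separates skin tones from neutral and cool backgrounds", {
  cfg <- SegmentationConfig()
  # neutral grey sits on the a* = b* = 128 axis: background (128 <= 131)
  expect_equal(sum(labThresholdMask(flatImage(4, 5, c(128, 128, 128)), cfg)),
               0)
  # saturated blue has b* far below the yellow threshold
  expect_equal(sum(labThresholdMask(flatImage(4, 5, c(0, 0, 255)), cfg)), 0)
  # half skin, half white: foreground exactly on the skin half
  img <- flatImage(10, 8, c(255, 255, 255))
  for (ch in 1:3) img[, 1:4, ch] <- c(220, 160, 130)[ch]
  m <- labThresholdMask(img, cfg)
  expect_equal(unname(m[, 1:4]), matrix(1L, 10, 4))
  expect_equal(unname(m[, 5:8]), matrix(0L, 10, 4))
})

test_that("thresholding is idempotent on a re-rendering of its own output", {
  img <- flatImage(20, 20, c(245, 245, 245))
  for (ch in 1:3) img[5:15, 8:14, ch] <- c(220, 160, 130)[ch]
  m1 <- labThresholdMask(img)
  img2 <- flatImage(20, 20, c(245, 245, 245))
  for (ch in 1:3) img2[, , ch][m1 == 1L] <- c(220, 160, 130)[ch]
  expect_identical(labThresholdMask(img2), m1)
})

test_that("OR-combined thresholds admit pixels passing either channel test", {
  # strong red but low b*: fails AND (b* too low), passes OR via a*
  magenta <- flatImage(3, 3, c(255, 0, 255))
  expect_equal(sum(labThresholdMask(magenta, SegmentationConfig())), 0)
  expect_equal(sum(labThresholdMask(magenta,
                                    SegmentationConfig(combine = "or"))), 9)
})

test_that("dilation matches the brute-force structuring-element definition", {
  cfg <- SegmentationConfig(dilationKernelSize = 3, dilationIterations = 1)
  empty <- matrix(0L, 9, 9)
  expect_identical(dilateMask(empty, cfg), empty)
  single <- matrix(0L, 9, 9); single[5, 5] <- 1L
  d1 <- dilateMask(single, cfg)
  expect_equal(sum(d1), 9)
  expect_equal(unname(d1[4:6, 4:6]), matrix(1L, 3, 3))
  # two blobs three pixels apart merge after two iterations
  two <- matrix(0L, 9, 12); two[4:5, 3] <- 1L; two[4:5, 7] <- 1L
  cfg2 <- SegmentationConfig(dilationIterations = 2)
  expect_equal(bruteComponentCount(dilateMask(two, cfg2)), 1L)
  # oracle equivalence + monotonicity on random masks
  set.seed(42)
  for (i in 1:8) {
    a <- matrix(as.integer(stats::runif(32 * 32) < 0.08), 32, 32)
    expect_identical(dilateMask(a, cfg), bruteDilate(a, 3L, 1L))
    b <- a; b[sample(which(b == 0L), 20)] <- 1L  # a subset of b
    expect_true(all(dilateMask(a, cfg) <= dilateMask(b, cfg)))
    expect_true(all(a <= dilateMask(a, cfg)))
  }
})

test_that("component extraction keeps feet and discards toes and noise", {
  m <- matrix(0L, 100, 100)
  m[30:80, 30:70] <- 1L                     # sole, area 2091
  for (j in seq(20, 70, by = 12)) m[12:15, j:(j + 3)] <- 1L  # five toes
  out <- extractFootprints(m, expectedFeet = "1")
  expect_length(out, 1)
  expect_equal(sum(out[[1]]), 51 * 41)
  expect_equal(bruteComponentCount(out[[1]]), 1L)
  # two equal blobs, auto: both returned, image-left foot first
  m2 <- matrix(0L, 100, 100)
  m2[20:80, 10:40] <- 1L; m2[20:80, 60:90] <- 1L
  out2 <- extractFootprints(m2, expectedFeet = "auto")
  expect_length(out2, 2)
  expect_lt(mean(which(out2[[1]] > 0, arr.ind = TRUE)[, 2]),
            mean(which(out2[[2]] > 0, arr.ind = TRUE)[, 2]))
  expect_error(extractFootprints(matrix(0L, 50, 50)), "no footprint")
  # asking for two feet when only one sizeable component exists
  expect_error(extractFootprints(m, expectedFeet = "2"), "two feet")
  # diagonal-only contact is one component under 8-connectivity (a
  # 4-connected labelling would split this into two sizeable components)
  m3 <- matrix(0L, 60, 60)
  m3[10:40, 10:30] <- 1L
  m3[41, 31] <- 1L; m3[42:55, 32:45] <- 1L
  out3 <- extractFootprints(m3, SegmentationConfig(
    minComponentFraction = 0.02), "auto")
  expect_length(out3, 1)
  expect_equal(sum(out3[[1]]), 31 * 21 + 1 + 14 * 14)
})

test_that("undilated silhouettes are recovered inside dilated components", {
  raw <- matrix(0L, 60, 60)
  raw[20:50, 20:40] <- 1L
  raw[10:14, 28:32] <- 1L  # toe blob, 6 px gap: merged by 3 dilations
  cfg <- SegmentationConfig(dilationIterations = 3)
  dil <- dilateMask(raw, cfg)
  expect_equal(bruteComponentCount(dil), 1L)
  out <- extractFootprints(dil, cfg, "1", undilated = raw)
  # returned mask is the sole at its thresholded (undilated) extent
  expect_equal(sum(out[[1]]), 31 * 21)
  expect_true(all(out[[1]] <= raw))
})

test_that("reference-square detection recovers the metric scale exactly", {
  img <- flatImage(200, 120, c(255, 255, 255))
  img[155:194, 40:79, ] <- 0  # 40 x 40, inside the bottom-quarter strip
  sc <- detectReferenceScale(img)
  expect_s4_class(sc, "CalibrationScale")
  expect_equal(pixelsPerCm(sc), 40)
  expect_equal(sc@squareAreaPx, 1600L)
  img2 <- flatImage(200, 120, c(255, 255, 255))
  img2[170:194, 10:34, ] <- 0  # 25 x 25
  expect_equal(pixelsPerCm(detectReferenceScale(img2)), 25)
  expect_error(detectReferenceScale(flatImage(50, 50, c(255, 255, 255))),
               "reference marker not found")
  # a dark square in the top half is outside the search region
  img3 <- flatImage(200, 120, c(255, 255, 255))
  img3[10:49, 40:79, ] <- 0
  expect_error(detectReferenceScale(img3), "reference marker not found")
})

test_that("segmentation configuration round-trips through YAML", {
  cfg <- SegmentationConfig(aThreshold = 120, dilationIterations = 3,
                            combine = "or")
  path <- tempfile(fileext = ".yaml")
  writeSegmentationConfig(cfg, path)
  cfg2 <- readSegmentationConfig(path)
  expect_equal(cfg2@aThreshold, 120)
  expect_equal(cfg2@dilationIterations, 3L)
  expect_equal(cfg2@combine, "or")
  expect_equal(cfg2@bThreshold, 131)  # untouched default
  # snake_case aliases accepted
  path2 <- tempfile(fileext = ".yaml")
  writeLines(c("a_threshold: 118", "red_threshold: 190"), path2)
  cfg3 <- readSegmentationConfig(path2)
  expect_equal(cfg3@aThreshold, 118)
  expect_equal(cfg3@redThreshold, 190)
  expect_error(readSegmentationConfig({
    p <- tempfile(); writeLines("bogus_key: 1", p); p
  }), "unknown config keys")
})

test_that("invalid segmentation configurations are rejected", {
  expect_error(SegmentationConfig(aThreshold = 300), "thresholds")
  expect_error(SegmentationConfig(dilationKernelSize = 4), "odd")
  expect_error(SegmentationConfig(minComponentFraction = 0), "fractions")
})
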