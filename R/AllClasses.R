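#' @import methods
NULL

#' Segmentation configuration
#'
#' Parameters controlling footprint segmentation and fiducial-marker
#' detection. The colour thresholds operate on the 8-bit offset-binary
#' encoding of the CIELAB a* and b* channels (neutral grey at 128): a pixel
#' is plantar-contact candidate when its encoded a* exceeds \code{aThreshold}
#' and its encoded b* exceeds \code{bThreshold} (with \code{combine = "and"};
#' set \code{combine = "or"} for the union of the two channel tests).
#' The reference square is sought as dark pixels (encoded red channel below
#' \code{redThreshold}) in the bottom \code{referenceSearchFraction} of the
#' image.
#'
#' @slot aThreshold numeric 8-bit level for the a* (green-red) channel,
#'   default 122.
#' @slot bThreshold numeric 8-bit level for the b* (blue-yellow) channel,
#'   default 131.
#' @slot redThreshold numeric 8-bit level below which a red-channel pixel
#'   counts as part of the dark reference square, default 183.
#' @slot dilationKernelSize odd integer side of the square structuring
#'   element, default 3.
#' @slot dilationIterations integer number of dilation passes, default 2.
#' @slot minComponentFraction fraction of total image area below which a
#'   connected component is discarded as noise/toes, default 0.01.
#' @slot referenceSearchFraction bottom fraction of the image scanned for
#'   the reference square, default 0.25.
#' @slot combine \code{"and"} or \code{"or"}; how the a* and b* channel
#'   tests are combined.
#'
#' @seealso [labThresholdMask()], [detectReferenceScale()],
#'   [readSegmentationConfig()]
#' @export
setClass("SegmentationConfig",
  representation(
    aThreshold = "numeric",
    bThreshold = "numeric",
    redThreshold = "numeric",
    dilationKernelSize = "integer",
    dilationIterations = "integer",
    minComponentFraction = "numeric",
    referenceSearchFraction = "numeric",
    combine = "character"
  ),
  prototype(
    aThreshold = 122, bThreshold = 131, redThreshold = 183,
    dilationKernelSize = 3L, dilationIterations = 2L,
    minComponentFraction = 0.01, referenceSearchFraction = 0.25,
    combine = "and"
  )
)

setValidity("SegmentationConfig", function(object) {
  msg <- character()
  thr <- c(a = object@aThreshold, b = object@bThreshold,
           red = object@redThreshold)
  if (any(thr < 0 | thr > 255))
    msg <- c(msg, "thresholds must lie in [0, 255]")
  if (length(object@dilationKernelSize) != 1L ||
      object@dilationKernelSize < 1L ||
      object@dilationKernelSize %% 2L == 0L)
    msg <- c(msg, "dilationKernelSize must be a positive odd integer")
  if (object@dilationIterations < 0L)
    msg <- c(msg, "dilationIterations must be >= 0")
  fr <- c(object@minComponentFraction, object@referenceSearchFraction)
  if (any(fr <= 0 | fr >= 1))
    msg <- c(msg, "fractions must lie in (0, 1)")
  if (!object@combine %in% c("and", "or"))
    msg <- c(msg, "combine must be \"and\" or \"or\"")
  if (length(msg)) msg else TRUE
})

#' Create a segmentation configuration
#'
#' @param aThreshold,bThreshold,redThreshold 8-bit channel thresholds.
#' @param dilationKernelSize odd side length of the square structuring
#'   element.
#' @param dilationIterations number of dilation passes.
#' @param minComponentFraction minimum component area as a fraction of the
#'   image area.
#' @param referenceSearchFraction bottom image fraction searched for the
#'   reference square.
#' @param combine how the a*/b* tests combine: \code{"and"} (default) or
#'   \code{"or"}.
#' @return A [SegmentationConfig-class] object.
#' @examples
#' cfg <- SegmentationConfig()
#' cfg
#' @export
SegmentationConfig <- function(aThreshold = 122, bThreshold = 131,
                               redThreshold = 183, dilationKernelSize = 3L,
                               dilationIterations = 2L,
                               minComponentFraction = 0.01,
                               referenceSearchFraction = 0.25,
                               combine = c("and", "or")) {
  combine <- match.arg(combine)
  new("SegmentationConfig",
      aThreshold = aThreshold, bThreshold = bThreshold,
      redThreshold = redThreshold,
      dilationKernelSize = as.integer(dilationKernelSize),
      dilationIterations = as.integer(dilationIterations),
      minComponentFraction = minComponentFraction,
      referenceSearchFraction = referenceSearchFraction,
      combine = combine)
}

#' Pixel-to-centimetre calibration
#'
#' Metric scale recovered from the 1 cm-squared fiducial sticker: the number
#' of pixels covered by the square gives its area in px^2, whose square root
#' is the side length in pixels, i.e. pixels per centimetre.
#'
#' @slot pixelsPerCm positive numeric scale factor.
#' @slot squareAreaPx integer pixel count of the detected square.
#' @seealso [detectReferenceScale()]
#' @export
setClass("CalibrationScale",
  representation(pixelsPerCm = "numeric", squareAreaPx = "integer"))

setValidity("CalibrationScale", function(object) {
  msg <- character()
  if (length(object@pixelsPerCm) != 1L || !is.finite(object@pixelsPerCm) ||
      object@pixelsPerCm <= 0)
    msg <- c(msg, "pixelsPerCm must be a positive finite number")
  if (length(object@squareAreaPx) != 1L || object@squareAreaPx < 1L)
    msg <- c(msg, "squareAreaPx must be a positive integer")
  if (length(msg) == 0 &&
      abs(object@pixelsPerCm - sqrt(object@squareAreaPx)) > 1e-6)
    msg <- c(msg, "pixelsPerCm must equal sqrt(squareAreaPx)")
  if (length(msg)) msg else TRUE
})

CalibrationScale <- function(squareAreaPx) {
  new("CalibrationScale", pixelsPerCm = sqrt(as.integer(squareAreaPx)),
      squareAreaPx = as.integer(squareAreaPx))
}

setClassUnion("CalibrationScaleOrNULL", c("CalibrationScale", "NULL"))

#' Three-zone partition of a footprint
#'
#' Half-open row intervals \code{[start, end)} (1-based rows, toes-up
#' convention) dividing the toeless footprint into forefoot, midfoot and
#' hindfoot bands of equal height; rows left over by integer division are
#' assigned to the hindfoot.
#'
#' @slot forefoot,midfoot,hindfoot integer(2) half-open row intervals,
#'   ordered top to bottom.
#' @seealso [partitionZones()]
#' @export
setClass("ZonePartition",
  representation(forefoot = "integer", midfoot = "integer",
                 hindfoot = "integer"))

setValidity("ZonePartition", function(object) {
  z <- rbind(object@forefoot, object@midfoot, object@hindfoot)
  if (ncol(z) != 2L) return("each zone must be an integer(2) [start, end)")
  if (any(z[, 2L] <= z[, 1L])) return("zones must be nonempty")
  if (z[1L, 2L] != z[2L, 1L] || z[2L, 2L] != z[3L, 1L])
    return("zones must be contiguous, ordered forefoot, midfoot, hindfoot")
  TRUE
})

#' A single segmented foot with orientation metadata
#'
#' @slot mask binary matrix (0/1), one 8-connected component, toes-up.
#' @slot side \code{"left"} or \code{"right"}.
#' @slot medialDirection \code{"image-left"} or \code{"image-right"}: which
#'   image side the medial (arch) border faces. Toes-up, a left foot has its
#'   medial border on image-right.
#' @slot zones [ZonePartition-class] of the mask.
#' @seealso [detectFeetAndSides()]
#' @export
setClass("FootRegion",
  representation(mask = "matrix", side = "character",
                 medialDirection = "character", zones = "ZonePartition"))

setValidity("FootRegion", function(object) {
  msg <- character()
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask must be binary (0/1)")
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be \"left\" or \"right\"")
  if (!object@medialDirection %in% c("image-left", "image-right"))
    msg <- c(msg, "medialDirection must be \"image-left\" or \"image-right\"")
  ok <- (object@side == "left") == (object@medialDirection == "image-right")
  if (length(msg) == 0 && !ok)
    msg <- c(msg, "side inconsistent with medialDirection (toes-up)")
  if (length(msg)) msg else TRUE
})

#' A measured line segment on the footprint
#'
#' Endpoints are pixel centres in (row, col) coordinates (1-based).
#' \code{lengthPx} is the Euclidean distance between the endpoints;
#' \code{lengthCm} is \code{lengthPx / pixelsPerCm} when a calibration is
#' available and \code{NA} otherwise.
#'
#' @slot start,end numeric(2) points (row, col).
#' @slot lengthPx,lengthCm numeric lengths.
#' @export
setClass("LineSegment",
  representation(start = "numeric", end = "numeric",
                 lengthPx = "numeric", lengthCm = "numeric"))

setValidity("LineSegment", function(object) {
  if (length(object@start) != 2L || length(object@end) != 2L)
    return("start and end must be numeric(2) (row, col)")
  if (abs(object@lengthPx - sqrt(sum((object@end - object@start)^2))) > 1e-6)
    return("lengthPx must equal the Euclidean distance of the endpoints")
  TRUE
})

LineSegment <- function(start, end, scale = NULL) {
  lpx <- euclideanDistance(start, end)
  lcm <- if (is.null(scale)) NA_real_ else lpx / scale@pixelsPerCm
  new("LineSegment", start = as.numeric(start), end = as.numeric(end),
      lengthPx = lpx, lengthCm = lcm)
}

#' Key points and named line segments of one footprint
#'
#' The nine anatomical key points located by the boundary scans and the six
#' line segments built from them:
#' \describe{
#'   \item{Q (q1 lateral, q2 medial)}{narrowest horizontal line of the
#'     midfoot.}
#'   \item{R (r2 lateral, r1 medial)}{widest horizontal line of the
#'     hindfoot.}
#'   \item{P (p1 lateral, p2 medial)}{widest horizontal line of the
#'     forefoot.}
#'   \item{T (t1 to f1)}{medial tangent line of the print, from the
#'     medial-most forefoot point to the medial-most hindfoot point.}
#'   \item{S (t1 to s1)}{medial forefoot point to the deepest medial arch
#'     point (s1 coincides with q2).}
#'   \item{F (f1 to s1)}{medial hindfoot point to the arch point, closing
#'     the triangle used for the arch angle.}
#' }
#'
#' @slot points 9 x 2 numeric matrix of (row, col) pixel coordinates with
#'   rownames q1, q2, r1, r2, p1, p2, t1, f1, s1.
#' @slot segments named list of [LineSegment-class]: Q, R, P, S, T, F.
#' @export
setClass("FootMeasurements",
  representation(points = "matrix", segments = "list"))

setValidity("FootMeasurements", function(object) {
  wantP <- c("q1", "q2", "r1", "r2", "p1", "p2", "t1", "f1", "s1")
  wantS <- c("Q", "R", "P", "S", "T", "F")
  if (!identical(rownames(object@points), wantP))
    return("points must have rownames q1,q2,r1,r2,p1,p2,t1,f1,s1")
  if (!identical(names(object@segments), wantS))
    return("segments must be named Q,R,P,S,T,F")
  s <- object@segments
  p <- object@points
  if (any(abs(s$S@start - p["t1", ]) > 1e-9) ||
      any(abs(s$S@end - p["s1", ]) > 1e-9))
    return("S must run from t1 to s1")
  if (any(abs(s$T@start - p["t1", ]) > 1e-9) ||
      any(abs(s$T@end - p["f1", ]) > 1e-9))
    return("T must run from t1 to f1")
  if (any(abs(s$F@start - p["f1", ]) > 1e-9) ||
      any(abs(s$F@end - p["s1", ]) > 1e-9))
    return("F must run from f1 to s1")
  for (nm in c("Q", "R", "P"))
    if (s[[nm]]@start[1L] != s[[nm]]@end[1L])
      return(sprintf("%s must be horizontal", nm))
  TRUE
})

#' The three footprint indices of one foot
#'
#' @slot staheli Staheli arch index Q/R (dimensionless; larger = flatter).
#' @slot chippauxSmirakPct Chippaux-Smirak index 100 Q/P (percent; larger =
#'   flatter).
#' @slot clarkeDeg Clarke's (arch) angle in degrees (larger = higher arch).
#' @seealso [staheliIndex()], [chippauxSmirak()], [clarkeAngle()]
#' @export
setClass("IndexSet",
  representation(staheli = "numeric", chippauxSmirakPct = "numeric",
                 clarkeDeg = "numeric"))

setValidity("IndexSet", function(object) {
  v <- c(object@staheli, object@chippauxSmirakPct, object@clarkeDeg)
  if (length(v) != 3L || !all(is.finite(v)))
    return("all three indices must be single finite numbers")
  if (object@staheli < 0 || object@chippauxSmirakPct < 0)
    return("Staheli and Chippaux-Smirak indices must be >= 0")
  if (object@clarkeDeg < 0 || object@clarkeDeg > 180)
    return("clarkeDeg must lie in [0, 180]")
  TRUE
})

IndexSet <- function(staheli, chippauxSmirakPct, clarkeDeg) {
  new("IndexSet", staheli = staheli, chippauxSmirakPct = chippauxSmirakPct,
      clarkeDeg = clarkeDeg)
}

#' Five-group classification table
#'
#' Numeric boundaries of the five deformity groups (1 Cavus, 2 Cavus-Normal,
#' 3 Normal, 4 Normal-Flat, 5 Flat) for each index. Staheli and
#' Chippaux-Smirak boundaries ascend (flatter feet get larger values); the
#' arch-angle boundaries descend. The Chippaux-Smirak boundaries are on the
#' fraction (0-1) scale; [classify()] divides the percent index by 100
#' before comparison.
#'
#' @slot staheliBreaks,csiBreaks,clarkeBreaks numeric(4) group boundaries.
#' @slot labels character(5) group labels.
#' @seealso [defaultClassificationTable()], [classify()]
#' @export
setClass("ClassificationTable",
  representation(staheliBreaks = "numeric", csiBreaks = "numeric",
                 clarkeBreaks = "numeric", labels = "character"))

setValidity("ClassificationTable", function(object) {
  msg <- character()
  for (nm in c("staheliBreaks", "csiBreaks", "clarkeBreaks")) {
    b <- slot(object, nm)
    if (length(b) != 4L || any(diff(b) <= 0))
      msg <- c(msg, sprintf("%s must be 4 strictly increasing numbers", nm))
  }
  if (length(object@labels) != 5L)
    msg <- c(msg, "labels must have length 5")
  if (length(msg)) msg else TRUE
})

#' Default five-group classification table
#'
#' Group boundaries: Staheli <0.3 / 0.3-0.4 / 0.4-0.7 / 0.7-0.8 / >0.8;
#' Chippaux-Smirak (fraction) <0.22 / 0.22-0.3 / 0.3-0.5 / 0.5-0.7 / >0.7;
#' arch angle >50 / 38-50 / 26-38 / 15-26 / <15 degrees. Shared boundary
#' values are resolved by half-open intervals: for the ascending indices the
#' lower bound is inclusive (0.4 is Normal for Staheli); for the descending
#' arch angle a boundary value joins the higher-arch group (50 degrees is
#' Cavus).
#'
#' @return A [ClassificationTable-class].
#' @examples
#' defaultClassificationTable()
#' @export
defaultClassificationTable <- function() {
  new("ClassificationTable",
      staheliBreaks = c(0.3, 0.4, 0.7, 0.8),
      csiBreaks = c(0.22, 0.3, 0.5, 0.7),
      clarkeBreaks = c(15, 26, 38, 50),
      labels = c("Cavus", "Cavus-Normal", "Normal", "Normal-Flat", "Flat"))
}

#' Per-index five-group classification of one foot
#'
#' @slot groupStaheli,groupCsi,groupClarke integer group 1-5.
#' @slot labels character(3) group labels, named staheli, csi, clarke.
#' @seealso [classify()]
#' @export
setClass("ClassificationResult",
  representation(groupStaheli = "integer", groupCsi = "integer",
                 groupClarke = "integer", labels = "character"))

setValidity("ClassificationResult", function(object) {
  g <- c(object@groupStaheli, object@groupCsi, object@groupClarke)
  if (any(g < 1L | g > 5L)) return("groups must lie in 1..5")
  if (length(object@labels) != 3L) return("labels must have length 3")
  TRUE
})

#' Complete analysis of one foot
#'
#' Returned (one per foot) by [analyzeFootprint()]: the segmented foot
#' region, its measured key points and segments, the three indices, their
#' five-group classification and the metric calibration (or NULL when the
#' image was analysed uncalibrated).
#'
#' @slot region [FootRegion-class].
#' @slot measurements [FootMeasurements-class].
#' @slot indices [IndexSet-class].
#' @slot classification [ClassificationResult-class].
#' @slot scale [CalibrationScale-class] or NULL.
#' @export
setClass("FootprintAnalysis",
  representation(region = "FootRegion", measurements = "FootMeasurements",
                 indices = "IndexSet", classification = "ClassificationResult",
                 scale = "CalibrationScaleOrNULL"))

#' Parameters of the synthetic footprint generator
#'
#' The silhouette is the union of a forefoot ellipse, a hindfoot ellipse and
#' the connecting trapezoid between their widest chords, minus a medial
#' circular-segment concavity of depth \code{archDepthPx} (0 = fully flat
#' contact; larger = deeper arch, up to a split print). Detached elliptical
#' toes sit above the forefoot and a dark reference square of side
#' \code{referenceSquareSidePx} is placed near the image bottom.
#'
#' @slot heightPx,widthPx canvas size in pixels.
#' @slot lengthPx toeless footprint length in pixels.
#' @slot forefootWidthPx,hindfootWidthPx widest forefoot/hindfoot extents.
#' @slot archDepthPx depth of the medial concavity in pixels.
#' @slot side \code{"left"} or \code{"right"}.
#' @slot toeCount,toeGapPx number of toes and their clearance from the sole.
#' @slot skinColor,backgroundColor sRGB triples in 0-255.
#' @slot referenceSquareSidePx side of the 1 cm fiducial square in pixels.
#' @slot rotationDeg in-plane rotation of the foot about its centre.
#' @slot noiseSd standard deviation of additive Gaussian pixel noise
#'   (8-bit units).
#' @slot seed integer RNG seed; renders are deterministic given the seed.
#' @seealso [generateFootprint()]
#' @export
setClass("FootShapeParams",
  representation(
    heightPx = "integer", widthPx = "integer", lengthPx = "integer",
    forefootWidthPx = "integer", hindfootWidthPx = "integer",
    archDepthPx = "numeric", side = "character", toeCount = "integer",
    toeGapPx = "integer", skinColor = "numeric", backgroundColor = "numeric",
    referenceSquareSidePx = "integer", rotationDeg = "numeric",
    noiseSd = "numeric", seed = "integer"
  ))

setValidity("FootShapeParams", function(object) {
  msg <- character()
  if (object@heightPx < 60L || object@widthPx < 40L)
    msg <- c(msg, "canvas too small")
  if (object@lengthPx < 30L)
    msg <- c(msg, "lengthPx must be >= 30")
  if (object@forefootWidthPx >= object@lengthPx ||
      object@hindfootWidthPx >= object@lengthPx)
    msg <- c(msg, "foot widths must be smaller than lengthPx")
  maxDepth <- (object@forefootWidthPx + object@hindfootWidthPx) / 2 - 4
  if (object@archDepthPx < 0 || object@archDepthPx > maxDepth)
    msg <- c(msg, sprintf(
      "archDepthPx must lie in [0, %.1f] (deeper would split the print)",
      maxDepth))
  if (!object@side %in% c("left", "right"))
    msg <- c(msg, "side must be \"left\" or \"right\"")
  if (object@toeCount < 0L || object@toeCount > 5L)
    msg <- c(msg, "toeCount must lie in 0..5")
  if (object@toeGapPx < 5L)
    msg <- c(msg, "toeGapPx must be >= 5 so dilation cannot bridge the toes")
  for (nm in c("skinColor", "backgroundColor")) {
    col <- slot(object, nm)
    if (length(col) != 3L || any(col < 0 | col > 255))
      msg <- c(msg, sprintf("%s must be an sRGB triple in 0..255", nm))
  }
  if (object@referenceSquareSidePx < 4L)
    msg <- c(msg, "referenceSquareSidePx must be >= 4")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  # layout feasibility: toes + foot + gap + marker must fit the canvas and
  # the marker must sit inside the bottom quarter
  lay <- try(.footLayout(object), silent = TRUE)
  if (inherits(lay, "try-error")) {
    msg <- c(msg, attr(lay, "condition")$message)
  }
  if (length(msg)) msg else TRUE
})

#' A rendered synthetic footprint with analytic ground truth
#'
#' Ground truth is derived from the continuous silhouette construction
#' before rasterisation (exact for \code{rotationDeg = 0}), so it is
#' independent of the segmentation and measurement code paths.
#'
#' @slot image H x W x 3 numeric array, 8-bit sRGB values.
#' @slot trueMask binary matrix: the toeless foot silhouette (no toes, no
#'   reference square).
#' @slot trueMeasures named list: Q, R, P pixel-centre widths (the exact
#'   value of the measured quantity on the known silhouette, computed
#'   analytically), their continuous counterparts continuousQ/R/P, key
#'   points t1, f1, s1, the zone row intervals and the foot side.
#' @slot trueIndices [IndexSet-class] computed from trueMeasures.
#' @slot params the generating [FootShapeParams-class].
#' @seealso [generateFootprint()]
#' @export
setClass("SyntheticFootprint",
  representation(image = "array", trueMask = "matrix",
                 trueMeasures = "list", trueIndices = "IndexSet",
                 params = "FootShapeParams"))

#' Precision report for a series of repeated measurements
#'
#' Summary of the one-sigma / three-sigma rule over repeated measurements of
#' one index on one foot: for approximately normal data about 68% of values
#' lie within one sample standard deviation of the mean and 99.7% within
#' three. "Outside" is strict: a value exactly k standard deviations from
#' the mean counts as inside.
#'
#' @slot n number of repeats.
#' @slot mean,sd sample mean and sample (n-1) standard deviation.
#' @slot nOutside1Sigma,nOutside3Sigma counts of values strictly outside.
#' @slot passes3Sigma TRUE when no value falls outside three sigma.
#' @seealso [sigmaRuleReport()]
#' @export
setClass("PrecisionReport",
  representation(n = "integer", mean = "numeric", sd = "numeric",
                 nOutside1Sigma = "integer", nOutside3Sigma = "integer",
                 passes3Sigma = "logical"))

setValidity("PrecisionReport", function(object) {
  if (object@nOutside1Sigma < object@nOutside3Sigma)
    return("values outside 3 sigma are necessarily outside 1 sigma")
  if (object@nOutside1Sigma > object@n)
    return("outside counts cannot exceed n")
  TRUE
})
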