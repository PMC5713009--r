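#' @name accessors
#' @title Accessors for footmorph result objects
#' @description Slot accessors for the S4 result classes; prefer these to
#'   direct slot access.
#' @param object an object of the documented class.
#' @return The slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("pixelsPerCm", function(object) standardGeneric("pixelsPerCm"))
#' @rdname accessors
#' @export
setMethod("pixelsPerCm", "CalibrationScale", function(object)
  object@pixelsPerCm)

#' @rdname accessors
#' @export
setGeneric("staheli", function(object) standardGeneric("staheli"))
#' @rdname accessors
#' @export
setMethod("staheli", "IndexSet", function(object) object@staheli)

#' @rdname accessors
#' @export
setGeneric("chippauxSmirakPct", function(object)
  standardGeneric("chippauxSmirakPct"))
#' @rdname accessors
#' @export
setMethod("chippauxSmirakPct", "IndexSet", function(object)
  object@chippauxSmirakPct)

#' @rdname accessors
#' @export
setGeneric("clarkeDeg", function(object) standardGeneric("clarkeDeg"))
#' @rdname accessors
#' @export
setMethod("clarkeDeg", "IndexSet", function(object) object@clarkeDeg)

#' @rdname accessors
#' @export
setGeneric("groups", function(object) standardGeneric("groups"))
#' @rdname accessors
#' @export
setMethod("groups", "ClassificationResult", function(object)
  c(staheli = object@groupStaheli, csi = object@groupCsi,
    clarke = object@groupClarke))

#' @rdname accessors
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))
#' @rdname accessors
#' @export
setMethod("measurements", "FootprintAnalysis", function(object)
  object@measurements)

#' @rdname accessors
#' @export
setGeneric("indices", function(object) standardGeneric("indices"))
#' @rdname accessors
#' @export
setMethod("indices", "FootprintAnalysis", function(object) object@indices)
#' @rdname accessors
#' @export
setMethod("indices", "SyntheticFootprint", function(object)
  object@trueIndices)

#' @rdname accessors
#' @export
setGeneric("classification", function(object)
  standardGeneric("classification"))
#' @rdname accessors
#' @export
setMethod("classification", "FootprintAnalysis", function(object)
  object@classification)

#' @rdname accessors
#' @export
setGeneric("calibration", function(object) standardGeneric("calibration"))
#' @rdname accessors
#' @export
setMethod("calibration", "FootprintAnalysis", function(object) object@scale)

#' @rdname accessors
#' @export
setGeneric("footSide", function(object) standardGeneric("footSide"))
#' @rdname accessors
#' @export
setMethod("footSide", "FootRegion", function(object) object@side)
#' @rdname accessors
#' @export
setMethod("footSide", "FootprintAnalysis", function(object)
  object@region@side)
#' @rdname accessors
#' @export
setMethod("footSide", "SyntheticFootprint", function(object)
  object@params@side)

#' @rdname accessors
#' @export
setGeneric("keyPoints", function(object) standardGeneric("keyPoints"))
#' @rdname accessors
#' @export
setMethod("keyPoints", "FootMeasurements", function(object) object@points)
#' @rdname accessors
#' @export
setMethod("keyPoints", "FootprintAnalysis", function(object)
  object@measurements@points)

#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname accessors
#' @export
setMethod("segments", "FootMeasurements", function(object) object@segments)
#' @rdname accessors
#' @export
setMethod("segments", "FootprintAnalysis", function(object)
  object@measurements@segments)

#' Segment lengths of a measured foot
#'
#' @param object a [FootMeasurements-class] or [FootprintAnalysis-class].
#' @param unit \code{"px"} or \code{"cm"}.
#' @return named numeric(6): lengths of Q, R, P, S, T, F.
#' @export
setGeneric("segmentLengths", function(object, unit = c("px", "cm"))
  standardGeneric("segmentLengths"))
#' @rdname segmentLengths
#' @export
setMethod("segmentLengths", "FootMeasurements", function(object,
    unit = c("px", "cm")) {
  unit <- match.arg(unit)
  vapply(object@segments, function(s)
    if (unit == "px") s@lengthPx else s@lengthCm, numeric(1))
})
#' @rdname segmentLengths
#' @export
setMethod("segmentLengths", "FootprintAnalysis", function(object,
    unit = c("px", "cm")) segmentLengths(object@measurements, unit))

setMethod("show", "SegmentationConfig", function(object) {
  cat("SegmentationConfig\n")
  cat(sprintf("  a* > %g %s b* > %g (8-bit offset-binary)\n",
              object@aThreshold, toupper(object@combine), object@bThreshold))
  cat(sprintf("  red-channel dark threshold: %g\n", object@redThreshold))
  cat(sprintf("  dilation: %dx%d square, %d iteration(s)\n",
              object@dilationKernelSize, object@dilationKernelSize,
              object@dilationIterations))
  cat(sprintf("  min component fraction: %g; reference search: bottom %g\n",
              object@minComponentFraction, object@referenceSearchFraction))
})

setMethod("show", "CalibrationScale", function(object) {
  cat(sprintf("CalibrationScale: %.3f px/cm (square area %d px)\n",
              object@pixelsPerCm, object@squareAreaPx))
})

setMethod("show", "IndexSet", function(object) {
  cat("IndexSet\n")
  cat(sprintf("  Staheli arch index:    %.4f\n", object@staheli))
  cat(sprintf("  Chippaux-Smirak index: %.2f %%\n",
              object@chippauxSmirakPct))
  cat(sprintf("  Clarke's angle:        %.2f deg\n", object@clarkeDeg))
})

setMethod("show", "ClassificationResult", function(object) {
  g <- groups(object)
  cat("ClassificationResult (1 Cavus .. 5 Flat)\n")
  cat(sprintf("  Staheli:         group %d (%s)\n", g["staheli"],
              object@labels[1L]))
  cat(sprintf("  Chippaux-Smirak: group %d (%s)\n", g["csi"],
              object@labels[2L]))
  cat(sprintf("  Clarke:          group %d (%s)\n", g["clarke"],
              object@labels[3L]))
})

setMethod("show", "FootRegion", function(object) {
  cat(sprintf("FootRegion: %s foot (medial %s), mask %d x %d, area %d px\n",
              object@side, object@medialDirection, nrow(object@mask),
              ncol(object@mask), sum(object@mask)))
})

setMethod("show", "FootMeasurements", function(object) {
  cat("FootMeasurements\n  segment lengths (px):\n")
  l <- segmentLengths(object, "px")
  for (nm in names(l)) cat(sprintf("    %s: %8.2f\n", nm, l[nm]))
})

setMethod("show", "FootprintAnalysis", function(object) {
  cat(sprintf("FootprintAnalysis of a %s foot\n", footSide(object)))
  if (!is.null(object@scale))
    cat(sprintf("  calibration: %.2f px/cm\n", object@scale@pixelsPerCm))
  else cat("  uncalibrated (pixel units only)\n")
  show(object@indices)
  show(object@classification)
})

setMethod("show", "FootShapeParams", function(object) {
  cat(sprintf(
    "FootShapeParams: %s foot, length %d px, widths %d/%d px, arch depth %.1f px\n",
    object@side, object@lengthPx, object@forefootWidthPx,
    object@hindfootWidthPx, object@archDepthPx))
  cat(sprintf("  canvas %d x %d, marker %d px, rotation %.1f deg, noise sd %.1f, seed %d\n",
              object@heightPx, object@widthPx, object@referenceSquareSidePx,
              object@rotationDeg, object@noiseSd, object@seed))
})

setMethod("show", "SyntheticFootprint", function(object) {
  cat(sprintf("SyntheticFootprint: %d x %d render, %s foot\n",
              dim(object@image)[1L], dim(object@image)[2L],
              object@params@side))
  show(object@trueIndices)
})

setMethod("show", "PrecisionReport", function(object) {
  cat(sprintf(
    "PrecisionReport: n=%d, mean=%.4f, sd=%.4f, outside 1s=%d, 3s=%d (%s)\n",
    object@n, object@mean, object@sd, object@nOutside1Sigma,
    object@nOutside3Sigma,
    if (object@passes3Sigma) "passes 3-sigma rule" else "FAILS 3-sigma rule"))
})
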