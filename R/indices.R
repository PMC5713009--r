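#' Staheli arch index
#'
#' Ratio of the narrowest midfoot width Q to the widest hindfoot width R.
#' Unit-independent: pixel and centimetre inputs give the same value. A
#' larger index means a flatter foot; 0 means no midfoot contact (extreme
#' cavus).
#'
#' @param Q narrowest midfoot width (>= 0).
#' @param R widest hindfoot width (> 0).
#' @return Q / R.
#' @examples
#' staheliIndex(2.5, 5)  # 0.5, a normal foot
#' @export
staheliIndex <- function(Q, R) {
  if (!is.finite(R) || R <= 0) stop("degenerate hindfoot: R must be > 0")
  if (!is.finite(Q) || Q < 0) stop("Q must be >= 0")
  Q / R
}

#' Chippaux-Smirak index
#'
#' Narrowest midfoot width Q over widest forefoot width P, in percent
#' (100 Q / P). The index decreases as the arch deepens.
#'
#' @param Q narrowest midfoot width (>= 0).
#' @param P widest forefoot width (> 0).
#' @return index in percent.
#' @examples
#' chippauxSmirak(2.5, 10)  # 25
#' @export
chippauxSmirak <- function(Q, P) {
  if (!is.finite(P) || P <= 0) stop("degenerate forefoot: P must be > 0")
  if (!is.finite(Q) || Q < 0) stop("Q must be >= 0")
  100 * Q / P
}

#' Clarke's (arch) angle from the S, T, F triangle
#'
#' The arch angle is defined at the medial forefoot point t1, between the
#' medial tangent line T (t1 to the medial hindfoot point f1) and the line S
#' (t1 to the deepest medial arch point s1); it is proportional to arch
#' height, from about 0 degrees for a fully flat print to above 50 degrees
#' for a cavus foot. By the law of cosines this is
#' \code{acos((S^2 + T^2 - F^2) / (2 S T))} -- the \code{"geometric"}
#' default. The \code{"as_printed"} variant instead evaluates
#' \code{acos((T^2 + F^2 - S^2) / (2 T F))}, i.e. the angle at the hindfoot
#' vertex f1; it is provided because instrument descriptions of the arch
#' angle sometimes quote the formula in that arrangement even though the
#' textual definition places the angle at the forefoot.
#'
#' @param S,T,F triangle side lengths (> 0), any common unit.
#' @param variant \code{"geometric"} (angle at t1, default) or
#'   \code{"as_printed"} (angle at f1).
#' @param tol tolerance on the triangle inequality: cosine magnitudes up to
#'   \code{1 + tol} are clamped, larger violations are an error. Clamped
#'   (collinear) configurations return 0 or 180 degrees with a warning.
#' @return angle in degrees.
#' @examples
#' clarkeAngle(1, 1, 1)                      # 60
#' clarkeAngle(5, 10, sqrt(45))              # 36.8699
#' clarkeAngle(5, 10, sqrt(45), "as_printed")  # 26.5651
#' @export
clarkeAngle <- function(S, T, F, variant = c("geometric", "as_printed"),
                        tol = 1e-8) {
  variant <- match.arg(variant)
  v <- c(S = S, T = T, F = F)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("S, T and F must be positive finite lengths")
  cosv <- if (variant == "geometric")
    (S^2 + T^2 - F^2) / (2 * S * T)
  else
    (T^2 + F^2 - S^2) / (2 * T * F)
  if (abs(cosv) > 1 + tol)
    stop(sprintf(
      "degenerate triangle: S=%g, T=%g, F=%g violate the triangle inequality",
      S, T, F))
  if (abs(cosv) >= 1) {
    warning("collinear key points: arch angle is ",
            if (cosv > 0) "0" else "180", " degrees")
    cosv <- sign(cosv)
  }
  acos(cosv) * 180 / pi
}

#' Compute the three indices from measured segments
#'
#' @param m a [FootMeasurements-class].
#' @param variant passed to [clarkeAngle()].
#' @return An [IndexSet-class].
#' @export
computeIndices <- function(m, variant = c("geometric", "as_printed")) {
  l <- segmentLengths(m, "px")
  IndexSet(staheli = staheliIndex(l[["Q"]], l[["R"]]),
           chippauxSmirakPct = chippauxSmirak(l[["Q"]], l[["P"]]),
           clarkeDeg = clarkeAngle(l[["S"]], l[["T"]], l[["F"]], variant))
}

# Ascending five-group lookup, lower bound inclusive:
# (-inf,b1) [b1,b2) [b2,b3) [b3,b4) [b4,inf)
.groupAscending <- function(x, breaks) {
  as.integer(findInterval(x, breaks) + 1L)
}

# Descending (arch angle): at a boundary the higher-arch (smaller) group
# wins: [b4,inf) -> 1, [b3,b4) -> 2, ..., (-inf,b1) -> 5
.groupDescending <- function(x, breaks) {
  as.integer(5L - findInterval(x, breaks))
}

#' Classify a single index value into the five groups
#'
#' @param x numeric value(s) of the index. Chippaux-Smirak values are given
#'   in percent (the natural output scale of [chippauxSmirak()]) and are
#'   compared against the table's fraction-scale boundaries after division
#'   by 100.
#' @param index \code{"staheli"}, \code{"csi"} or \code{"clarke"}.
#' @param table a [ClassificationTable-class].
#' @return integer group(s) in 1..5.
#' @export
classifyValue <- function(x, index = c("staheli", "csi", "clarke"),
                          table = defaultClassificationTable()) {
  index <- match.arg(index)
  switch(index,
    staheli = .groupAscending(x, table@staheliBreaks),
    csi = .groupAscending(x / 100, table@csiBreaks),
    clarke = .groupDescending(x, table@clarkeBreaks))
}

#' Classify an index set into the five deformity groups
#'
#' Assigns each of the three indices to one of the five groups (1 Cavus,
#' 2 Cavus-Normal, 3 Normal, 4 Normal-Flat, 5 Flat) of the classification
#' table. The Chippaux-Smirak index is compared on the fraction scale
#' (percent / 100), matching the table's printed ranges.
#'
#' @param ind an [IndexSet-class].
#' @param table a [ClassificationTable-class].
#' @return A [ClassificationResult-class].
#' @examples
#' classify(IndexSet(0.5, 25, 55))  # Normal / Cavus-Normal / Cavus
#' @export
classify <- function(ind, table = defaultClassificationTable()) {
  gs <- classifyValue(ind@staheli, "staheli", table)
  gc <- classifyValue(ind@chippauxSmirakPct, "csi", table)
  ga <- classifyValue(ind@clarkeDeg, "clarke", table)
  new("ClassificationResult", groupStaheli = gs, groupCsi = gc,
      groupClarke = ga,
      labels = c(staheli = table@labels[gs], csi = table@labels[gc],
                 clarke = table@labels[ga]))
}

#' Analyse a footprint image end to end
#'
#' Runs the full pipeline: CIELAB thresholding, dilation, component
#' extraction (dilation decides connectivity, the thresholded silhouette is
#' measured), fiducial calibration, side detection, zone partitioning,
#' key-point scans, index computation and five-group classification. The
#' analysis is deterministic for a fixed image and configuration.
#'
#' @param image H x W x 3 array of 8-bit sRGB values (toes-up), or a file
#'   path readable by [readFootprintImage()].
#' @param config a [SegmentationConfig-class].
#' @param expectedFeet \code{"auto"}, \code{"1"} or \code{"2"}.
#' @param table a [ClassificationTable-class].
#' @param variant arch-angle variant, see [clarkeAngle()].
#' @param allowUncalibrated when TRUE, a missing reference marker downgrades
#'   to a warning and lengths are reported in pixels only.
#' @param forceSide optional side override passed to [detectFeetAndSides()].
#' @return list of [FootprintAnalysis-class], one per foot (image-left foot
#'   first).
#' @examples
#' sample <- generateFootprint(FootShapeParams(seed = 7))
#' res <- analyzeFootprint(sample@image)
#' res[[1]]
#' @export
analyzeFootprint <- function(image, config = SegmentationConfig(),
                             expectedFeet = c("auto", "1", "2"),
                             table = defaultClassificationTable(),
                             variant = c("geometric", "as_printed"),
                             allowUncalibrated = FALSE, forceSide = NULL) {
  if (is.character(image)) image <- readFootprintImage(image)
  expectedFeet <- match.arg(as.character(expectedFeet), c("auto", "1", "2"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  raw <- stage("segmentation", labThresholdMask(image, config))
  dil <- stage("segmentation", dilateMask(raw, config))
  feetMasks <- stage("segmentation",
                     extractFootprints(dil, config, expectedFeet,
                                       undilated = raw))
  scale <- tryCatch(detectReferenceScale(image, config), error = function(e) {
    if (allowUncalibrated) {
      warning("reference marker not found; reporting pixel units only")
      NULL
    } else stop("[calibration] ", conditionMessage(e), call. = FALSE)
  })
  feet <- stage("geometry", detectFeetAndSides(feetMasks,
                                               forceSide = forceSide))
  lapply(feet, function(foot) {
    m <- stage("geometry", measureSegments(foot, scale))
    ind <- stage("indices", computeIndices(m, variant))
    new("FootprintAnalysis", region = foot, measurements = m,
        indices = ind, classification = classify(ind, table), scale = scale)
  })
}

#' JSON report of a footprint analysis
#'
#' Serialises one or more per-foot analyses into a JSON document with a
#' stable key order, suitable for diffing across runs: key points, segment
#' lengths in px and (when calibrated) cm, the three indices, the five-group
#' classification and an echo of the segmentation configuration. Repeated
#' analyses of the same image produce byte-identical reports; pass
#' \code{timestamp = TRUE} to embed the generation time (which breaks that
#' property on purpose).
#'
#' @param results list of [FootprintAnalysis-class] (as returned by
#'   [analyzeFootprint()]).
#' @param config the [SegmentationConfig-class] used.
#' @param path optional output file.
#' @param timestamp embed the generation time (default FALSE).
#' @return the JSON string, invisibly when \code{path} is given.
#' @export
footprintReport <- function(results, config = SegmentationConfig(),
                            path = NULL, timestamp = FALSE) {
  feet <- lapply(results, function(x) {
    m <- x@measurements
    pts <- lapply(seq_len(nrow(m@points)), function(i)
      list(row = m@points[i, 1L], col = m@points[i, 2L]))
    names(pts) <- rownames(m@points)
    segs <- lapply(m@segments, function(s) {
      out <- list(lengthPx = round(s@lengthPx, 6))
      if (!is.na(s@lengthCm)) out$lengthCm <- round(s@lengthCm, 6)
      out
    })
    g <- groups(x@classification)
    entry <- list(
      side = footSide(x),
      points = pts,
      segments = segs,
      indices = list(staheli = round(x@indices@staheli, 6),
                     chippauxSmirakPct = round(x@indices@chippauxSmirakPct, 6),
                     clarkeDeg = round(x@indices@clarkeDeg, 6)),
      classification = list(
        staheli = list(group = unname(g["staheli"]),
                       label = unname(x@classification@labels[1L])),
        chippauxSmirak = list(group = unname(g["csi"]),
                              label = unname(x@classification@labels[2L])),
        clarke = list(group = unname(g["clarke"]),
                      label = unname(x@classification@labels[3L]))))
    if (!is.null(x@scale))
      entry <- append(entry, list(calibration = list(
        pixelsPerCm = round(x@scale@pixelsPerCm, 6),
        squareAreaPx = x@scale@squareAreaPx)), after = 1L)
    entry
  })
  doc <- list(
    tool = "footmorph",
    feet = feet,
    config = list(aThreshold = config@aThreshold,
                  bThreshold = config@bThreshold,
                  redThreshold = config@redThreshold,
                  dilationKernelSize = config@dilationKernelSize,
                  dilationIterations = config@dilationIterations,
                  minComponentFraction = config@minComponentFraction,
                  referenceSearchFraction = config@referenceSearchFraction,
                  combine = config@combine))
  if (timestamp) doc$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
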