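#' Euclidean distance between two pixel points
#'
#' Points are (row, col) pixel centres; the distance is
#' \code{sqrt((row2 - row1)^2 + (col2 - col1)^2)}.
#'
#' @param a,b numeric(2) points (row, col).
#' @return nonnegative distance in pixels.
#' @examples
#' euclideanDistance(c(0, 0), c(3, 4))  # 5
#' @export
euclideanDistance <- function(a, b) {
  sqrt(sum((as.numeric(b) - as.numeric(a))^2))
}

#' Partition a footprint into forefoot, midfoot and hindfoot bands
#'
#' Splits the mask's bounding rows (toes-up: forefoot at the top) into three
#' contiguous bands of equal height; rows left over by the integer division
#' go to the hindfoot band.
#'
#' @param mask binary matrix, single component, toes-up.
#' @return A [ZonePartition-class] with half-open row intervals.
#' @examples
#' m <- matrix(0L, 100, 20); m[11:21, 5:15] <- 1L
#' partitionZones(m)  # bands of 3, 3 and 5 rows
#' @export
partitionZones <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  if (length(rows) == 0L) stop("footprint too small: empty mask")
  top <- min(rows); bot <- max(rows)
  h <- bot - top + 1L
  if (h < 3L) stop("footprint too small: bounding height below 3 rows")
  third <- h %/% 3L
  new("ZonePartition",
      forefoot = as.integer(c(top, top + third)),
      midfoot = as.integer(c(top + third, top + 2L * third)),
      hindfoot = as.integer(c(top + 2L * third, bot + 1L)))
}

# Maximal inward deviation of one lateral boundary from the chord joining
# its extreme points over the midfoot rows; the concavity measure behind
# side detection.
.boundaryConcavity <- function(mask, zone, sideOf = c("left", "right")) {
  sideOf <- match.arg(sideOf)
  rows <- zone[1L]:(zone[2L] - 1L)
  prof <- lapply(rows, function(r) {
    cc <- which(mask[r, ] > 0)
    if (length(cc) == 0L) return(NULL)
    c(r, if (sideOf == "left") min(cc) else max(cc))
  })
  prof <- do.call(rbind, prof)
  if (is.null(prof) || nrow(prof) < 3L) return(0)
  r0 <- prof[1L, ]; r1 <- prof[nrow(prof), ]
  chord <- r0[2L] + (prof[, 1L] - r0[1L]) / max(1, r1[1L] - r0[1L]) *
    (r1[2L] - r0[2L])
  dev <- if (sideOf == "left") prof[, 2L] - chord else chord - prof[, 2L]
  max(0, max(dev))
}

#' Determine foot side from the medial-arch concavity
#'
#' For each single-component mask, the medial direction is the image side
#' whose midfoot boundary shows the deeper concavity (maximal horizontal
#' inset of the boundary relative to the chord between its extreme midfoot
#' points). Under the toes-up convention a medial border on image-right
#' means a left foot and vice versa. For two-foot images the medial sides
#' must face each other.
#'
#' @param masks list of binary matrices, each one 8-connected component,
#'   toes-up (as returned by [extractFootprints()]).
#' @param ambiguityTol minimum concavity difference (px) below which the
#'   side is reported ambiguous.
#' @param forceSide optional \code{"left"}/\code{"right"} override (single
#'   foot only), for prints with no usable arch cue.
#' @return list of [FootRegion-class] objects.
#' @export
detectFeetAndSides <- function(masks, ambiguityTol = 1.5, forceSide = NULL) {
  if (!is.list(masks)) masks <- list(masks)
  feet <- lapply(masks, function(m) {
    zones <- partitionZones(m)
    if (!is.null(forceSide)) {
      side <- match.arg(forceSide, c("left", "right"))
      medial <- if (side == "left") "image-right" else "image-left"
    } else {
      cl <- .boundaryConcavity(m, zones@midfoot, "left")
      cr <- .boundaryConcavity(m, zones@midfoot, "right")
      if (abs(cl - cr) < ambiguityTol)
        stop("side ambiguous: no dominant medial concavity ",
             sprintf("(left %.2f px vs right %.2f px)", cl, cr))
      medial <- if (cr > cl) "image-right" else "image-left"
      side <- if (medial == "image-right") "left" else "right"
    }
    new("FootRegion", mask = m, side = side, medialDirection = medial,
        zones = zones)
  })
  if (length(feet) == 2L) {
    # list is ordered image-left foot first; medial borders must face inward
    if (!(feet[[1L]]@medialDirection == "image-right" &&
          feet[[2L]]@medialDirection == "image-left"))
      stop("side detection inconsistent: medial sides of the two feet ",
           "do not face each other")
  }
  feet
}

.zoneRows <- function(foot, zone = c("forefoot", "midfoot", "hindfoot")) {
  zone <- match.arg(zone)
  z <- slot(foot@zones, zone)
  z[1L]:(z[2L] - 1L)
}

#' Row-by-row width profile of a footprint zone
#'
#' For every zone row containing foreground, records the lateral-most
#' (outer) and medial-most (inner) foreground columns and the width between
#' their pixel centres, \code{|innerCol - outerCol|} (so a one-pixel-wide
#' row has width 0).
#'
#' @param foot a [FootRegion-class].
#' @param zone \code{"forefoot"}, \code{"midfoot"} or \code{"hindfoot"}.
#' @return data.frame with columns row, outerCol, innerCol, widthPx.
#' @export
widthProfile <- function(foot, zone = c("forefoot", "midfoot", "hindfoot")) {
  zone <- match.arg(zone)
  rows <- .zoneRows(foot, zone)
  medialRight <- foot@medialDirection == "image-right"
  prof <- lapply(rows, function(r) {
    cc <- which(foot@mask[r, ] > 0)
    if (length(cc) == 0L) return(NULL)
    inner <- if (medialRight) max(cc) else min(cc)
    outer <- if (medialRight) min(cc) else max(cc)
    data.frame(row = r, outerCol = outer, innerCol = inner,
               widthPx = abs(inner - outer))
  })
  prof <- do.call(rbind, prof)
  if (is.null(prof)) stop("empty zone: no foreground rows in ", zone)
  prof
}

# Extremal-width row with the deterministic tie-break: nearest the zone's
# centre row, then the smaller row index.
.extremeWidthRow <- function(prof, zone, what = c("min", "max")) {
  what <- match.arg(what)
  target <- if (what == "min") min(prof$widthPx) else max(prof$widthPx)
  cand <- prof[prof$widthPx == target, , drop = FALSE]
  center <- (zone[1L] + zone[2L] - 1L) / 2
  cand <- cand[order(abs(cand$row - center), cand$row), , drop = FALSE]
  cand[1L, ]
}

#' Locate the Q, R and P lines
#'
#' \code{findQ} finds the narrowest horizontal line of the midfoot (the arch
#' waist), \code{findR} the widest line of the hindfoot and \code{findP} the
#' widest line of the forefoot. Ties across rows are broken by the row
#' nearest the zone's centre row, then by the smaller row index.
#'
#' @param foot a [FootRegion-class].
#' @return A [LineSegment-class] from the lateral to the medial endpoint.
#' @seealso [widthProfile()], [measureSegments()]
#' @export
findQ <- function(foot) {
  prof <- widthProfile(foot, "midfoot")
  r <- .extremeWidthRow(prof, foot@zones@midfoot, "min")
  LineSegment(c(r$row, r$outerCol), c(r$row, r$innerCol))
}

#' @rdname findQ
#' @export
findR <- function(foot) {
  prof <- widthProfile(foot, "hindfoot")
  r <- .extremeWidthRow(prof, foot@zones@hindfoot, "max")
  LineSegment(c(r$row, r$outerCol), c(r$row, r$innerCol))
}

#' @rdname findQ
#' @export
findP <- function(foot) {
  prof <- widthProfile(foot, "forefoot")
  r <- .extremeWidthRow(prof, foot@zones@forefoot, "max")
  LineSegment(c(r$row, r$outerCol), c(r$row, r$innerCol))
}

#' Locate the arch-angle key points t1, f1 and s1
#'
#' The arch (Clarke's) angle is read off the medial print border:
#' \code{t1} is the medial-most boundary pixel of the forefoot zone,
#' \code{f1} the medial-most boundary pixel of the hindfoot zone -- their
#' connecting line T is the medial tangent of the print -- and \code{s1}
#' is the deepest point of the medial arch concavity, identified with the
#' medial endpoint of the narrowest midfoot line (q2). A flat print leaves
#' s1 near the tangent (angle toward 0), a high arch pulls it laterally
#' (angle above 50 degrees). Medial-most ties are broken by the smaller
#' row index.
#'
#' @param foot a [FootRegion-class].
#' @return named list of numeric(2) points t1, f1, s1.
#' @export
findClarkePoints <- function(foot) {
  medialMost <- function(zone) {
    prof <- widthProfile(foot, zone)
    best <- if (foot@medialDirection == "image-right")
      prof[prof$innerCol == max(prof$innerCol), , drop = FALSE]
    else
      prof[prof$innerCol == min(prof$innerCol), , drop = FALSE]
    best <- best[order(best$row), , drop = FALSE]
    c(best$row[1L], best$innerCol[1L])
  }
  q <- findQ(foot)
  list(t1 = medialMost("forefoot"), f1 = medialMost("hindfoot"),
       s1 = as.numeric(q@end))
}

#' Assemble the full set of foot measurements
#'
#' Builds the nine key points and the six segments Q, R, P, S, T, F of one
#' foot, with lengths in pixels and -- when a calibration is supplied -- in
#' centimetres.
#'
#' @param foot a [FootRegion-class].
#' @param scale a [CalibrationScale-class] or NULL for pixel units only.
#' @return A [FootMeasurements-class].
#' @export
measureSegments <- function(foot, scale = NULL) {
  Q <- findQ(foot); R <- findR(foot); P <- findP(foot)
  cp <- findClarkePoints(foot)
  pts <- rbind(q1 = Q@start, q2 = Q@end, r1 = R@end, r2 = R@start,
               p1 = P@start, p2 = P@end, t1 = cp$t1, f1 = cp$f1,
               s1 = cp$s1)
  colnames(pts) <- c("row", "col")
  seg <- function(a, b) LineSegment(pts[a, ], pts[b, ], scale)
  new("FootMeasurements", points = pts,
      segments = list(Q = seg("q1", "q2"), R = seg("r2", "r1"),
                      P = seg("p1", "p2"), S = seg("t1", "s1"),
                      T = seg("t1", "f1"), F = seg("f1", "s1")))
}

# Pixels of the line between two (row, col) points, for annotation overlays.
.linePixels <- function(a, b) {
  n <- max(2L, ceiling(max(abs(b - a))) * 2L)
  t <- seq(0, 1, length.out = n)
  cbind(round(a[1L] + t * (b[1L] - a[1L])),
        round(a[2L] + t * (b[2L] - a[2L])))
}

#' Draw measured lines and key points onto an image
#'
#' Renders the six segments and nine key points over the source image and
#' optionally writes the result as PNG: Q/R/P in blue, the arch-angle
#' triangle S/T/F in red, key points as green 3 x 3 squares.
#'
#' @param image H x W x 3 array of 8-bit sRGB values.
#' @param m a [FootMeasurements-class].
#' @param path optional output PNG path.
#' @return the annotated array, invisibly when \code{path} is given.
#' @export
annotateFootprint <- function(image, m, path = NULL) {
  h <- dim(image)[1L]; w <- dim(image)[2L]
  put <- function(img, px, colr) {
    px <- px[px[, 1L] >= 1 & px[, 1L] <= h & px[, 2L] >= 1 & px[, 2L] <= w,
             , drop = FALSE]
    for (ch in 1:3) img[cbind(px, ch)] <- colr[ch]
    img
  }
  for (nm in c("Q", "R", "P")) {
    s <- m@segments[[nm]]
    image <- put(image, .linePixels(s@start, s@end), c(30, 60, 230))
  }
  for (nm in c("S", "T", "F")) {
    s <- m@segments[[nm]]
    image <- put(image, .linePixels(s@start, s@end), c(230, 40, 40))
  }
  for (i in seq_len(nrow(m@points))) {
    p <- round(m@points[i, ])
    sq <- as.matrix(expand.grid(p[1L] + (-1:1), p[2L] + (-1:1)))
    image <- put(image, sq, c(30, 200, 60))
  }
  if (!is.null(path)) {
    writeFootprintImage(image, path)
    return(invisible(image))
  }
  image
}
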