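#' Read an RGB footprint image
#'
#' Reads a PNG or JPEG file into the package's working representation: an
#' H x W x 3 numeric array of 8-bit sRGB values (0-255), row 1 at the top.
#' Greyscale images are expanded to three identical channels; an alpha
#' channel is dropped.
#'
#' @param path file path to a PNG or JPEG image.
#' @return H x W x 3 numeric array in 0..255.
#' @seealso [writeMask()], [analyzeFootprint()]
#' @export
readFootprintImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 2L) {
    a <- array(rep(a, 3L), dim = c(d[1L], d[2L], 3L))
  } else if (d[3L] > 3L) {
    a <- a[, , 1:3, drop = FALSE]
  } else if (d[3L] < 3L) {
    a <- array(rep(a[, , 1L], 3L), dim = c(d[1L], d[2L], 3L))
  }
  # EBImage stores (x, y, c) in 0..1; transpose to (row, col, channel)
  round(255 * aperm(a, c(2L, 1L, 3L)))
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels (1) are written as 255, background as 0.
#'
#' @param mask binary matrix.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(mask, path)
  invisible(path)
}

#' Write an RGB array as PNG
#' @param image H x W x 3 array in 0..255.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFootprintImage <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

# sRGB (0..255) -> 8-bit offset-binary CIELAB channels (D65 white point).
# Returns list of H x W matrices L, a, b with the OpenCV-style encoding
# L* * 255/100, a* + 128, b* + 128.
.labEncode <- function(image) {
  d <- dim(image)
  rgb <- matrix(as.numeric(image), ncol = 3L) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1L] * 255 / 100, d[1L], d[2L]),
       a = matrix(lab[, 2L] + 128, d[1L], d[2L]),
       b = matrix(lab[, 3L] + 128, d[1L], d[2L]))
}

#' Binarize an image by CIELAB a*/b* thresholding
#'
#' Converts the sRGB image to CIELAB (D65) and encodes a* and b* as 8-bit
#' offset-binary values with the neutral axis at 128. A pixel is foreground
#' when its encoded a* exceeds \code{aThreshold} and (or, with
#' \code{combine = "or"}) its encoded b* exceeds \code{bThreshold}.
#' Luminance is ignored, which makes the test robust to illumination: skin
#' tones sit well above both thresholds on the red and yellow axes while
#' white, grey and black backgrounds sit on the neutral axis (a* = b* = 128)
#' and any blue cast falls below the b* threshold.
#'
#' @param image H x W x 3 array of 8-bit sRGB values.
#' @param config a [SegmentationConfig-class].
#' @return binary H x W matrix (1 = plantar-contact candidate).
#' @examples
#' img <- array(0, dim = c(4, 4, 3))
#' img[, , 1] <- 220; img[, , 2] <- 160; img[, , 3] <- 130  # skin tone
#' sum(labThresholdMask(img, SegmentationConfig()))  # 16: all foreground
#' @export
labThresholdMask <- function(image, config = SegmentationConfig()) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3L] == 3L)
  lab <- .labEncode(image)
  fg <- if (config@combine == "and")
    (lab$a > config@aThreshold) & (lab$b > config@bThreshold)
  else
    (lab$a > config@aThreshold) | (lab$b > config@bThreshold)
  m <- matrix(0L, nrow(fg), ncol(fg))
  m[fg] <- 1L
  m
}

#' Morphologically dilate a binary mask
#'
#' Dilation with a square structuring element of side
#' \code{dilationKernelSize}, applied \code{dilationIterations} times. It
#' expands the thresholded footprint to close small holes and reconnect
#' regions lost at the colour-thresholding stage; the foreground never
#' shrinks.
#'
#' @param mask binary matrix.
#' @param config a [SegmentationConfig-class].
#' @return binary matrix of the same shape.
#' @export
dilateMask <- function(mask, config = SegmentationConfig()) {
  k <- config@dilationKernelSize
  if (k == 1L || config@dilationIterations == 0L) return(mask)
  brush <- EBImage::makeBrush(k, shape = "box")
  out <- mask
  for (i in seq_len(config@dilationIterations))
    out <- EBImage::imageData(EBImage::dilate(out, brush))
  m <- matrix(0L, nrow(mask), ncol(mask))
  m[out > 0] <- 1L
  m
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected; labels
# that touch diagonally are merged with a union-find pass, then relabelled
# 1..n by decreasing size (ties: smaller original label first). Fully
# vectorised apart from the union loop over distinct diagonal label pairs.
.labelComponents <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n == 0L) return(matrix(0L, nrow(lab), ncol(lab)))
  parent <- seq_len(n)
  if (n > 1L) {
    h <- nrow(lab); w <- ncol(lab)
    a <- lab[-h, -w]; b <- lab[-1L, -1L]   # down-right diagonal pairs
    c_ <- lab[-1L, -w]; d <- lab[-h, -1L]  # up-right diagonal pairs
    pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                   cbind(as.vector(c_), as.vector(d)))
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    if (nrow(pairs)) {
      pairs <- unique(pairs)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- parent
  repeat {                       # vectorised path compression
    nxt <- parent[root]
    if (identical(nxt, root)) break
    root <- nxt
  }
  areas <- as.vector(rowsum(tabulate(lab[lab > 0L], nbins = n),
                            root, reorder = TRUE))
  roots <- sort(unique(root))
  ord <- order(-areas, roots)    # new id 1 = largest component
  newId <- integer(length(roots))
  newId[ord] <- seq_along(roots)
  map <- newId[match(root, roots)]
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

#' Extract footprint components from a binary mask
#'
#' Keeps the dominant connected components (8-connectivity) of the mask and
#' discards small ones -- detached toes, the reference square if it leaked
#' into the mask, and speckle noise. With \code{expectedFeet = "1"} the
#' largest component is kept, with \code{"2"} the two largest, and with
#' \code{"auto"} every component covering at least
#' \code{minComponentFraction} of the image area (capped at two, by size).
#'
#' When the mask was dilated for connectivity, pass the pre-dilation mask as
#' \code{undilated}: each returned footprint is then the set of original
#' thresholded pixels inside the selected dilated component (largest
#' connected piece thereof), i.e. the dilation decides which pixels belong
#' together while the returned silhouette keeps the thresholded boundary.
#'
#' @param mask binary matrix (possibly dilated).
#' @param config a [SegmentationConfig-class].
#' @param expectedFeet \code{"auto"}, \code{"1"} or \code{"2"}.
#' @param undilated optional binary matrix: the mask before dilation.
#' @return list of binary matrices, one per foot, each a single 8-connected
#'   component on the full image grid. For two feet the list is ordered by
#'   centroid column (image-left foot first).
#' @export
extractFootprints <- function(mask, config = SegmentationConfig(),
                              expectedFeet = c("auto", "1", "2"),
                              undilated = NULL) {
  expectedFeet <- match.arg(as.character(expectedFeet),
                            c("auto", "1", "2"))
  lab <- .labelComponents(mask)
  n <- max(lab)
  if (n == 0L) stop("no footprint found")
  areas <- tabulate(lab[lab > 0], nbins = n)
  minArea <- config@minComponentFraction * length(mask)
  keep <- switch(expectedFeet,
    "1" = 1L,
    "2" = {
      if (n < 2L || areas[2L] < minArea)
        stop("no footprint found: expected two feet, found fewer")
      1:2
    },
    "auto" = {
      big <- which(areas >= minArea)
      if (length(big) == 0L) stop("no footprint found")
      head(big, 2L)
    })
  if (areas[keep[1L]] < minArea) stop("no footprint found")
  out <- lapply(keep, function(i) {
    m <- matrix(0L, nrow(mask), ncol(mask))
    m[lab == i] <- 1L
    if (!is.null(undilated)) {
      m <- m * (undilated > 0)
      sub <- .labelComponents(m)
      m <- matrix(0L, nrow(mask), ncol(mask))
      m[sub == 1L] <- 1L
    }
    m
  })
  if (length(out) == 2L) {
    cols <- vapply(out, function(m) mean(which(m > 0, arr.ind = TRUE)[, 2L]),
                   numeric(1))
    out <- out[order(cols)]
  }
  out
}

#' Detect the 1 cm-squared reference marker and derive the metric scale
#'
#' Scans the bottom \code{referenceSearchFraction} of the image for dark
#' pixels in the red channel (value below \code{redThreshold}), takes the
#' largest 8-connected dark component as the fiducial square, and sets
#' pixels-per-centimetre to the square root of its pixel count.
#'
#' @param image H x W x 3 array of 8-bit sRGB values.
#' @param config a [SegmentationConfig-class].
#' @return A [CalibrationScale-class].
#' @examples
#' img <- array(255, dim = c(100, 60, 3))
#' img[85:94, 20:29, ] <- 0  # 10 x 10 black square near the bottom
#' pixelsPerCm(detectReferenceScale(img))  # 10
#' @export
detectReferenceScale <- function(image, config = SegmentationConfig()) {
  h <- dim(image)[1L]
  from <- h - floor(h * config@referenceSearchFraction) + 1L
  if (from > h) from <- h
  strip <- image[from:h, , 1L, drop = TRUE]
  if (is.null(dim(strip))) strip <- matrix(strip, nrow = 1L)
  dark <- matrix(0L, nrow(strip), ncol(strip))
  dark[strip < config@redThreshold] <- 1L
  lab <- .labelComponents(dark)
  if (max(lab) == 0L)
    stop("reference marker not found")
  CalibrationScale(sum(lab == 1L))
}

#' Load a segmentation configuration from YAML
#'
#' Reads a YAML mapping whose keys match the [SegmentationConfig()]
#' arguments (snake_case aliases such as \code{a_threshold} are accepted);
#' absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A [SegmentationConfig-class].
#' @export
readSegmentationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  alias <- c(a_threshold = "aThreshold", b_threshold = "bThreshold",
             red_threshold = "redThreshold",
             dilation_kernel_size = "dilationKernelSize",
             dilation_iterations = "dilationIterations",
             min_component_fraction = "minComponentFraction",
             reference_search_fraction = "referenceSearchFraction")
  names(y) <- ifelse(names(y) %in% names(alias), alias[names(y)], names(y))
  known <- names(formals(SegmentationConfig))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(SegmentationConfig, y)
}

#' Write a segmentation configuration to YAML
#' @param config a [SegmentationConfig-class].
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
writeSegmentationConfig <- function(config, path) {
  yaml::write_yaml(list(
    aThreshold = config@aThreshold, bThreshold = config@bThreshold,
    redThreshold = config@redThreshold,
    dilationKernelSize = config@dilationKernelSize,
    dilationIterations = config@dilationIterations,
    minComponentFraction = config@minComponentFraction,
    referenceSearchFraction = config@referenceSearchFraction,
    combine = config@combine), path)
  invisible(path)
}
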