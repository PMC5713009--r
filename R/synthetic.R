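#' Construct synthetic footprint parameters
#'
#' Defaults render a left adult footprint at roughly 40 px/cm on a
#' 600 x 320 canvas: a 420 px (10.5 cm) toeless print, forefoot 180 px and
#' hindfoot 140 px wide, with a 40 px (1 cm) fiducial square near the
#' bottom. \code{archDepthPx} sweeps the flat-to-cavus continuum; the
#' default 88 px yields a mid-normal print.
#'
#' @param heightPx,widthPx canvas size.
#' @param lengthPx toeless footprint length.
#' @param forefootWidthPx,hindfootWidthPx widest zone extents.
#' @param archDepthPx medial concavity depth (0 = flat).
#' @param side \code{"left"} or \code{"right"}.
#' @param toeCount,toeGapPx toes rendered and their clearance.
#' @param skinColor,backgroundColor sRGB triples (0-255). The default skin
#'   tone sRGB(220, 160, 130) encodes to CIELAB a* = 146.7, b* = 152.5
#'   (8-bit offset-binary), comfortably above the 122/131 segmentation
#'   thresholds, while the near-white background stays on the neutral axis.
#' @param referenceSquareSidePx fiducial side length.
#' @param rotationDeg in-plane rotation; ground truth is exact at 0 and
#'   approximate otherwise.
#' @param noiseSd additive Gaussian pixel noise, 8-bit units.
#' @param seed RNG seed for the noise.
#' @return A [FootShapeParams-class].
#' @export
FootShapeParams <- function(heightPx = 600L, widthPx = 321L,
                            lengthPx = 420L, forefootWidthPx = 180L,
                            hindfootWidthPx = 140L, archDepthPx = 88,
                            side = c("left", "right"), toeCount = 5L,
                            toeGapPx = 12L,
                            skinColor = c(220, 160, 130),
                            backgroundColor = c(245, 245, 245),
                            referenceSquareSidePx = 40L, rotationDeg = 0,
                            noiseSd = 0, seed = 1L) {
  side <- match.arg(side)
  new("FootShapeParams",
      heightPx = as.integer(heightPx), widthPx = as.integer(widthPx),
      lengthPx = as.integer(lengthPx),
      forefootWidthPx = as.integer(forefootWidthPx),
      hindfootWidthPx = as.integer(hindfootWidthPx),
      archDepthPx = as.numeric(archDepthPx), side = side,
      toeCount = as.integer(toeCount), toeGapPx = as.integer(toeGapPx),
      skinColor = as.numeric(skinColor),
      backgroundColor = as.numeric(backgroundColor),
      referenceSquareSidePx = as.integer(referenceSquareSidePx),
      rotationDeg = as.numeric(rotationDeg), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed))
}

# Canvas layout shared by the renderer and the validity method. Errors here
# surface as parameter-validation messages.
.footLayout <- function(p) {
  L <- p@lengthPx
  toeLen <- round(0.11 * L) + 10L
  footTop <- 12L + toeLen + p@toeGapPx        # first foot row
  footBot <- footTop + L - 1L
  k <- p@referenceSquareSidePx
  markerTop <- p@heightPx - k - 12L
  if (markerTop <= footBot + 10L)
    stop("canvas heightPx too small for footprint plus reference square")
  if (markerTop < p@heightPx - floor(0.25 * p@heightPx) + 1L)
    stop("reference square would sit above the bottom quarter of the image")
  halfW <- max(p@forefootWidthPx, p@hindfootWidthPx) / 2
  if (p@widthPx < 2 * halfW + 24)
    stop("canvas widthPx too small for the footprint width")
  # foot axis on an integer column; with an odd canvas width this is the
  # exact mirror axis, making side = "right" a pixel-perfect reflection
  c0 <- (p@widthPx + 1L) %/% 2L
  markerLeft <- c0 - floor(k / 2)
  if (p@side == "right")   # mirror the marker too, about column c0
    markerLeft <- 2L * c0 - (markerLeft + k - 1L)
  list(footTop = footTop, footBot = footBot, c0 = c0,
       centerRow = footTop + (L - 1) / 2, markerTop = markerTop,
       markerLeft = markerLeft, k = k)
}

# Continuous silhouette half-widths on the integer row grid u = 0..L-1
# (u = 0 at the toeless print's top). Returns lateral and medial half-width
# vectors (medial after subtracting the arch circular segment) plus the
# construction constants.
.footProfile <- function(p) {
  L <- p@lengthPx
  bf <- p@forefootWidthPx / 2
  bh <- p@hindfootWidthPx / 2
  af <- max(6, round(0.21 * L))
  ah <- max(6, round(0.19 * L))
  rf <- af
  rh <- L - 1 - ah
  u <- 0:(L - 1)
  w <- numeric(L)
  iF <- u <= rf
  w[iF] <- bf * sqrt(pmax(0, 1 - ((u[iF] - rf) / af)^2))
  iM <- u > rf & u < rh
  w[iM] <- bf + (bh - bf) * (u[iM] - rf) / (rh - rf)
  iH <- u >= rh
  w[iH] <- bh * sqrt(pmax(0, 1 - ((u[iH] - rh) / ah)^2))
  wlat <- w
  wmed <- w
  d <- p@archDepthPx
  rm <- (rf + rh) / 2
  if (d > 0.5) {
    cc <- 0.41 * (rh - rf)              # half-chord of the arch segment
    rho <- (cc^2 + d^2) / (2 * d)       # circle radius for depth d
    centerV <- w[round(rm) + 1L] - d + rho
    inside <- abs(u - rm) < cc
    bound <- centerV - sqrt(pmax(0, rho^2 - (u - rm)^2))
    wmed[inside] <- pmin(w[inside], bound[inside])
  }
  list(u = u, wlat = wlat, wmed = wmed, af = af, ah = ah, rf = rf, rh = rh,
       rm = rm, bf = bf, bh = bh)
}

# Toe ellipses in unrotated foot coordinates (u down the foot, v medial-
# positive). Columns: uc, vc, ru, rv per toe.
.toeSpec <- function(p, prof) {
  if (p@toeCount == 0L) return(NULL)
  scale <- p@lengthPx / 420
  rv <- c(9, 7.5, 6.5, 6, 5.5)[seq_len(p@toeCount)] * scale   # vertical
  rh_ <- c(8, 6.5, 6, 5.5, 5)[seq_len(p@toeCount)] * scale    # horizontal
  # big toe medial-most, spread across the forefoot
  vc <- seq(0.72, -0.72, length.out = 5L)[seq_len(p@toeCount)] * prof$bf
  # hug the forefoot ellipse: boundary row above the forefoot at offset vc
  ub <- prof$af * (1 - sqrt(pmax(0, 1 - (vc / prof$bf)^2)))
  uc <- ub - p@toeGapPx - rv
  cbind(uc = uc, vc = vc, ru = rv, rvh = rh_)
}

# Ground-truth measurements from the silhouette construction, using the
# same zone and tie-break rules as the measurement module but never
# touching raster or segmentation code. Key points live on the pixel grid,
# so extremal rows are selected from the analytically quantised boundary
# offsets floor(half-width) -- the pixel-centre sampling of the continuous
# profile -- while the reported Q/R/P widths stay continuous. Coordinates
# are unrotated, left-foot orientation (medial = +v); the caller maps them
# to image coordinates.
.groundTruth <- function(p, prof, lay) {
  L <- p@lengthPx
  third <- L %/% 3L
  eps <- 1e-9
  latOff <- floor(prof$wlat + eps)   # lateral boundary pixel offset
  medOff <- floor(prof$wmed + eps)   # medial boundary pixel offset
  widthQ <- latOff + medOff          # pixel-centre width per row
  width <- prof$wlat + prof$wmed     # continuous width per row
  zones <- list(forefoot = c(0L, third), midfoot = c(third, 2L * third),
                hindfoot = c(2L * third, L))
  pick <- function(zone, values, what) {
    idx <- (zone[1L]:(zone[2L] - 1L)) + 1L
    v <- values[idx]
    target <- if (what == "min") min(v) else max(v)
    cand <- idx[v == target]
    center <- (zone[1L] + zone[2L] - 1) / 2
    cand[order(abs((cand - 1L) - center), cand)][1L]
  }
  iQ <- pick(zones$midfoot, widthQ, "min")
  iR <- pick(zones$hindfoot, widthQ, "max")
  iP <- pick(zones$forefoot, widthQ, "max")
  # medial tangent points: maximal medial offset, ties to the smaller row
  pickMed <- function(zone) {
    idx <- (zone[1L]:(zone[2L] - 1L)) + 1L
    v <- medOff[idx]
    sort(idx[v == max(v)])[1L]
  }
  iT <- pickMed(zones$forefoot)
  iF <- pickMed(zones$hindfoot)
  # unrotated points (u, v), medial positive, on pixel centres
  t1 <- c(prof$u[iT], medOff[iT])
  f1 <- c(prof$u[iF], medOff[iF])
  s1 <- c(prof$u[iQ], medOff[iQ])
  ang <- function(a, b) {
    cosv <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }
  clarke <- ang(s1 - t1, f1 - t1)
  list(Q = widthQ[iQ], R = widthQ[iR], P = widthQ[iP],
       continuousQ = width[iQ], continuousR = width[iR],
       continuousP = width[iP],
       rowQ = prof$u[iQ], t1 = t1, f1 = f1, s1 = s1,
       zones = zones, clarkeDeg = clarke)
}

# Map unrotated foot coordinates (u, v) to image (row, col).
.toImage <- function(uv, p, lay) {
  s <- if (p@side == "left") 1 else -1
  th <- p@rotationDeg * pi / 180
  dr <- uv[1L] - (p@lengthPx - 1) / 2
  dc <- s * uv[2L]
  c(lay$centerRow + dr * cos(th) - dc * sin(th),
    lay$c0 + dr * sin(th) + dc * cos(th))
}

#' Generate a synthetic footprint image with ground truth
#'
#' Renders a parametric plantar footprint: the toeless silhouette is the
#' union of a forefoot ellipse, a hindfoot ellipse and the trapezoid joining
#' their widest chords, minus a medial circular-segment concavity of depth
#' \code{archDepthPx}; detached elliptical toes sit above the forefoot and a
#' dark square of side \code{referenceSquareSidePx} is placed near the image
#' bottom on a light background. Ground-truth widths, key points and indices
#' are derived from the continuous construction before rasterisation, so
#' they are independent of the package's segmentation and measurement code.
#'
#' @param params a [FootShapeParams-class].
#' @return A [SyntheticFootprint-class].
#' @examples
#' s <- generateFootprint(FootShapeParams(archDepthPx = 0, seed = 3))
#' chippauxSmirakPct(indices(s))  # flat foot: close to 89%
#' @export
generateFootprint <- function(params) {
  p <- params
  validObject(p)
  lay <- .footLayout(p)
  prof <- .footProfile(p)
  gt <- .groundTruth(p, prof, lay)
  H <- p@heightPx; W <- p@widthPx
  s <- if (p@side == "left") 1 else -1
  th <- p@rotationDeg * pi / 180

  # unrotated foot coordinates of every canvas pixel above the marker
  rows <- 1:(lay$markerTop - 2L)
  grid <- expand.grid(row = rows, col = 1:W)
  dr <- grid$row - lay$centerRow
  dc <- grid$col - lay$c0
  u <- dr * cos(th) + dc * sin(th) + (p@lengthPx - 1) / 2
  v <- s * (-dr * sin(th) + dc * cos(th))

  inRange <- u >= 0 & u <= p@lengthPx - 1
  wl <- rep(-1, length(u)); wm <- rep(-1, length(u))
  wl[inRange] <- stats::approx(prof$u, prof$wlat, u[inRange])$y
  wm[inRange] <- stats::approx(prof$u, prof$wmed, u[inRange])$y
  footPix <- inRange & v >= -wl - 1e-9 & v <= wm + 1e-9

  toePix <- rep(FALSE, length(u))
  toes <- .toeSpec(p, prof)
  if (!is.null(toes)) {
    for (i in seq_len(nrow(toes))) {
      toePix <- toePix |
        ((u - toes[i, "uc"]) / toes[i, "ru"])^2 +
        ((v - toes[i, "vc"]) / toes[i, "rvh"])^2 <= 1
    }
  }

  img <- array(rep(p@backgroundColor, each = H * W), dim = c(H, W, 3L))
  skin <- footPix | toePix
  idxRow <- grid$row[skin]; idxCol <- grid$col[skin]
  for (ch in 1:3)
    img[cbind(idxRow, idxCol, ch)] <- p@skinColor[ch]
  mrows <- lay$markerTop:(lay$markerTop + lay$k - 1L)
  mcols <- lay$markerLeft:(lay$markerLeft + lay$k - 1L)
  img[mrows, mcols, ] <- 5

  if (p@noiseSd > 0) {
    seedKeep <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(seedKeep))
        assign(".Random.seed", seedKeep, envir = globalenv())
    }, add = TRUE)
    set.seed(p@seed)
    img <- img + stats::rnorm(length(img), 0, p@noiseSd)
  }
  img <- round(pmin(pmax(img, 0), 255))

  trueMask <- matrix(0L, H, W)
  trueMask[cbind(grid$row[footPix], grid$col[footPix])] <- 1L

  toImg <- function(uv) .toImage(uv, p, lay)
  measures <- list(
    Q = gt$Q, R = gt$R, P = gt$P,
    continuousQ = gt$continuousQ, continuousR = gt$continuousR,
    continuousP = gt$continuousP,
    t1 = toImg(gt$t1), f1 = toImg(gt$f1), s1 = toImg(gt$s1),
    rowQ = lay$footTop + gt$rowQ,
    zones = lapply(gt$zones, function(z) z + lay$footTop),
    side = p@side,
    exact = p@rotationDeg == 0)
  trueIdx <- IndexSet(staheli = gt$Q / gt$R,
                      chippauxSmirakPct = 100 * gt$Q / gt$P,
                      clarkeDeg = gt$clarkeDeg)
  new("SyntheticFootprint", image = img, trueMask = trueMask,
      trueMeasures = measures, trueIndices = trueIdx, params = p)
}

# Per-group Chippaux-Smirak target ranges (fraction scale) used when a
# cohort subject is drawn from a deformity group; kept slightly inside the
# classification boundaries so a subject's group is unambiguous.
.csiGroupRanges <- list(c(0.10, 0.21), c(0.225, 0.295), c(0.31, 0.49),
                        c(0.51, 0.69), c(0.71, 0.84))

# Foot geometry for a target Chippaux-Smirak fraction: with forefoot and
# hindfoot half-widths bf, bh the waist width is bf + bh - depth and the
# forefoot width 2 bf, so depth = bf + bh - 2 bf csi.
.archDepthForCsi <- function(csi, bf, bh) {
  maxCsi <- (bf + bh) / (2 * bf) - 0.03   # keep a visible concavity
  csi <- min(csi, maxCsi)
  max(4, bf + bh - 2 * bf * csi)
}

#' Generate a cohort of synthetic footprints with repeated measures
#'
#' Emulates a repeated-measures precision study: \code{nSubjects} subjects
#' are drawn from a mix of the five deformity groups, each standing on the
#' podoscope \code{repeats} times; between repeats the stance is jittered
#' (small rotation, vertical placement, slight arch-depth variation and
#' pixel noise). Each of the \code{nSubjects * repeats} samples is rendered
#' and, by default, run through [analyzeFootprint()] to yield the measured
#' index series that feed the sigma-rule precision analysis.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param repeats images per subject (>= 2).
#' @param groupMix numeric(5) mix proportions over groups 1 (cavus) to 5
#'   (flat); normalised to sum to 1.
#' @param seed cohort RNG seed.
#' @param analyze run the analysis pipeline on every sample (default TRUE);
#'   with FALSE the measures table contains the ground-truth indices
#'   instead, which is faster and useful for generator-only checks.
#' @param jitterRotationDeg,jitterArchPx,noiseSd stance-jitter magnitudes.
#' @param keepSamples also return the rendered [SyntheticFootprint-class]
#'   objects (memory-hungry; default FALSE).
#' @param config segmentation configuration used when \code{analyze = TRUE}.
#' @return list with \code{samples} (one metadata row per rendered image,
#'   including the ground-truth indices), \code{measures} (long-format
#'   repeated-measures table: subject, side, index, repeat, value) and,
#'   when requested, \code{objects}.
#' @examples
#' coh <- generateCohort(nSubjects = 2, repeats = 2, seed = 1,
#'                       analyze = FALSE)
#' nrow(coh$samples)  # 4
#' @export
generateCohort <- function(nSubjects = 40L, repeats = 5L,
                           groupMix = rep(0.2, 5), seed = 1L,
                           analyze = TRUE, jitterRotationDeg = 1.2,
                           jitterArchPx = 1.5, noiseSd = 3,
                           keepSamples = FALSE,
                           config = SegmentationConfig()) {
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  if (repeats < 2L) stop("repeats must be >= 2 for a precision analysis")
  if (length(groupMix) != 5L || any(groupMix < 0) || sum(groupMix) <= 0)
    stop("invalid mix proportions: need 5 nonnegative values, sum > 0")
  groupMix <- groupMix / sum(groupMix)

  seedKeep <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(seedKeep))
      assign(".Random.seed", seedKeep, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  samples <- list(); measures <- list(); objects <- list()
  for (subj in seq_len(nSubjects)) {
    grp <- sample.int(5L, 1L, prob = groupMix)
    csiT <- stats::runif(1, .csiGroupRanges[[grp]][1L],
                         .csiGroupRanges[[grp]][2L])
    L <- round(stats::runif(1, 390, 440))
    wf <- round(L * stats::runif(1, 0.41, 0.45))
    wh <- round(L * stats::runif(1, 0.32, 0.35))
    side <- sample(c("left", "right"), 1L)
    baseArch <- .archDepthForCsi(csiT, wf / 2, wh / 2)
    for (rep_ in seq_len(repeats)) {
      arch <- min(max(4, baseArch + stats::rnorm(1, 0, jitterArchPx)),
                  (wf + wh) / 2 - 4)
      sampleSeed <- (seed * 1000003 + subj * 7919 + rep_ * 104729) %%
        2000000000
      par <- FootShapeParams(
        lengthPx = L, forefootWidthPx = wf, hindfootWidthPx = wh,
        archDepthPx = arch, side = side,
        toeGapPx = 12L + sample(-2:2, 1L),
        rotationDeg = stats::runif(1, -jitterRotationDeg,
                                   jitterRotationDeg),
        noiseSd = noiseSd, seed = sampleSeed)
      sf <- generateFootprint(par)
      ti <- sf@trueIndices
      samples[[length(samples) + 1L]] <- data.frame(
        subject = subj, rep = rep_, side = side, group = grp,
        lengthPx = L, archDepthPx = arch,
        trueStaheli = staheli(ti), trueCsiPct = chippauxSmirakPct(ti),
        trueClarkeDeg = clarkeDeg(ti), seed = sampleSeed)
      vals <- if (analyze) {
        # the simulated stance side is known; pass it through, since the
        # flattest prints under heavy noise can have a genuinely ambiguous
        # arch cue (the analysis contract lets the caller force the side)
        res <- analyzeFootprint(sf@image, config = config,
                                expectedFeet = "1",
                                forceSide = side)[[1L]]
        c(staheli = staheli(res@indices),
          csi = chippauxSmirakPct(res@indices),
          clarke = clarkeDeg(res@indices))
      } else {
        c(staheli = staheli(ti), csi = chippauxSmirakPct(ti),
          clarke = clarkeDeg(ti))
      }
      measures[[length(measures) + 1L]] <- data.frame(
        subject = subj, side = side,
        index = c("staheli", "csi", "clarke"),
        "repeat" = rep_, value = unname(vals),
        check.names = FALSE)
      if (keepSamples) objects[[length(objects) + 1L]] <- sf
    }
  }
  out <- list(samples = do.call(rbind, samples),
              measures = do.call(rbind, measures))
  if (keepSamples) out$objects <- objects
  out
}
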