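# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive results from first principles (set definitions,
# exhaustive scans) rather than calling package internals.

# Dilation by the set definition: a pixel is foreground iff any input
# foreground pixel lies within the (k x k) structuring-element window.
bruteDilate <- function(mask, k = 3L, iterations = 1L) {
  r <- (k - 1L) %/% 2L
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  for (it in seq_len(iterations)) {
    src <- out
    out <- matrix(0L, h, w)
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        i0 <- max(1L, i - r); i1 <- min(h, i + r)
        j0 <- max(1L, j - r); j1 <- min(w, j + r)
        if (any(src[i0:i1, j0:j1] > 0)) out[i, j] <- 1L
      }
    }
  }
  out
}

# Exhaustive per-row scan: extreme foreground columns and pixel-centre
# width for every nonempty row in [rowFrom, rowTo].
bruteRowScan <- function(mask, rowFrom, rowTo, medialRight = TRUE) {
  res <- NULL
  for (r in rowFrom:rowTo) {
    cc <- which(mask[r, ] > 0)
    if (length(cc) == 0L) next
    inner <- if (medialRight) max(cc) else min(cc)
    outer <- if (medialRight) min(cc) else max(cc)
    res <- rbind(res, c(row = r, outer = outer, inner = inner,
                        width = abs(inner - outer)))
  }
  res
}

# 8-connected component count by breadth-first flood fill.
bruteComponentCount <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (mask[i, j] > 0 && !seen[i, j]) {
      count <- count + 1L
      queue <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (di in -1:1) for (dj in -1:1) {
          ii <- p[1L] + di; jj <- p[2L] + dj
          if (ii >= 1L && ii <= h && jj >= 1L && jj <= w &&
              mask[ii, jj] > 0 && !seen[ii, jj]) {
            seen[ii, jj] <- TRUE
            queue[[length(queue) + 1L]] <- c(ii, jj)
          }
        }
      }
    }
  }
  count
}

# Random blob mask with a guaranteed vertical spine so every zone has
# foreground in every row.
randomBlobMask <- function(h = 64L, w = 64L, density = 0.1) {
  m <- matrix(0L, h, w)
  spineL <- sample(10:25, h, replace = TRUE)
  spineR <- sample(35:55, h, replace = TRUE)
  for (r in seq_len(h)) m[r, spineL[r]:spineR[r]] <- 1L
  extra <- matrix(stats::runif(h * w) < density, h, w)
  m[extra] <- 1L
  m
}

# Wrap a mask in a FootRegion without running side detection (random masks
# have no anatomical arch).
asFootRegion <- function(mask, side = "left") {
  medial <- if (side == "left") "image-right" else "image-left"
  new("FootRegion", mask = mask, side = side, medialDirection = medial,
      zones = partitionZones(mask))
}

# Uniform-colour test image from an sRGB triple.
flatImage <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3L))
}

# Deterministic parameter sets spanning the five deformity groups, ten
# samples per group. Arch depth is derived from a target Chippaux-Smirak
# fraction via the construction arithmetic (waist = bf + bh - depth).
# Default noise follows the generator default (clean renders); noisy
# operation is exercised by the cohort, IoU and determinism tests.
groupSpanningParams <- function(perGroup = 10L, noiseSd = 0,
                                baseSeed = 100L) {
  targets <- list(c(0.10, 0.20), c(0.23, 0.29), c(0.32, 0.48),
                  c(0.52, 0.68), c(0.72, 0.82))
  out <- list()
  for (g in 1:5) {
    csis <- seq(targets[[g]][1L], targets[[g]][2L],
                length.out = perGroup)
    for (i in seq_len(perGroup)) {
      bf <- 90; bh <- 70
      d <- max(4, bf + bh - 2 * bf * csis[i])
      out[[length(out) + 1L]] <- FootShapeParams(
        archDepthPx = d, side = if (i %% 2L == 0L) "right" else "left",
        noiseSd = noiseSd, seed = baseSeed + g * 100L + i)
    }
  }
  out
}
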