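#' Longitudinal patient-history store
#'
#' Index values from successive consultations are kept in an append-only,
#' human-auditable CSV file (one row per patient, visit date and foot) so a
#' clinician can track the effect of a treatment over time. The file starts
#' with a schema-version header comment.
#'
#' @param storePath CSV file path; created on first add.
#' @param patient patient identifier.
#' @param date visit date, ISO 8601 (\code{YYYY-MM-DD}).
#' @param side \code{"left"} or \code{"right"}.
#' @param indexSet an [IndexSet-class] (or the three values via
#'   \code{staheli}, \code{csiPct}, \code{clarkeDeg}).
#' @param staheli,csiPct,clarkeDeg index values, used when
#'   \code{indexSet} is missing.
#' @param table classification table used to store the groups alongside.
#' @return \code{storePath}, invisibly.
#' @examples
#' store <- tempfile(fileext = ".csv")
#' historyAdd(store, "p1", "2024-03-01", "left", IndexSet(0.5, 40, 35))
#' historyRead(store)
#' @export
historyAdd <- function(storePath, patient, date, side, indexSet = NULL,
                       staheli = NULL, csiPct = NULL, clarkeDeg = NULL,
                       table = defaultClassificationTable()) {
  side <- match.arg(side, c("left", "right"))
  if (is.na(as.Date(date, format = "%Y-%m-%d")))
    stop("date must be ISO 8601 (YYYY-MM-DD): ", date)
  if (!is.null(indexSet)) {
    staheli <- indexSet@staheli
    csiPct <- indexSet@chippauxSmirakPct
    clarkeDeg <- indexSet@clarkeDeg
  }
  if (is.null(staheli) || is.null(csiPct) || is.null(clarkeDeg))
    stop("provide an IndexSet or all three index values")
  cls <- classify(IndexSet(staheli, csiPct, clarkeDeg), table)
  g <- groups(cls)
  rec <- data.frame(patient = as.character(patient),
                    date = as.character(date), side = side,
                    staheli = round(staheli, 6), csiPct = round(csiPct, 6),
                    clarkeDeg = round(clarkeDeg, 6),
                    groupStaheli = g["staheli"], groupCsi = g["csi"],
                    groupClarke = g["clarke"])
  if (file.exists(storePath)) {
    old <- historyRead(storePath)
    dup <- old$patient == rec$patient & old$date == rec$date &
      old$side == rec$side
    if (any(dup))
      stop(sprintf("duplicate history record for (%s, %s, %s)",
                   rec$patient, rec$date, rec$side))
    con <- file(storePath, "a")
    utils::write.table(rec, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, qmethod = "double")
    close(con)
  } else {
    con <- file(storePath, "w")
    writeLines("# footmorph history v1", con)
    utils::write.table(rec, con, sep = ",", row.names = FALSE,
                       col.names = TRUE, qmethod = "double")
    close(con)
  }
  invisible(storePath)
}

#' @rdname historyAdd
#' @export
historyRead <- function(storePath) {
  if (!file.exists(storePath)) stop("no history store at ", storePath)
  utils::read.csv(storePath, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(patient = "character", date = "character"))
}

#' Plot a patient's index history
#'
#' Writes a three-panel PNG (Staheli, Chippaux-Smirak, arch angle against
#' visit date), one line per foot, with the normal-range band of each index
#' shaded for orientation.
#'
#' @param storePath history CSV (see [historyAdd()]).
#' @param patient patient identifier to plot.
#' @param outPng output PNG path.
#' @param table classification table supplying the normal-range bands.
#' @return \code{outPng}, invisibly.
#' @export
historyPlot <- function(storePath, patient, outPng,
                        table = defaultClassificationTable()) {
  h <- historyRead(storePath)
  h <- h[h$patient == as.character(patient), , drop = FALSE]
  if (nrow(h) == 0L) stop("no records for patient ", patient)
  h$date <- as.Date(h$date)
  h <- h[order(h$date), , drop = FALSE]
  panels <- list(
    list(col = "staheli", lab = "Staheli arch index",
         normal = table@staheliBreaks[2:3]),
    list(col = "csiPct", lab = "Chippaux-Smirak index (%)",
         normal = 100 * table@csiBreaks[2:3]),
    list(col = "clarkeDeg", lab = "Clarke's angle (deg)",
         normal = table@clarkeBreaks[2:3]))
  grDevices::png(outPng, width = 900, height = 1000, res = 110)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(3, 1), mar = c(4, 4.5, 2, 1))
  for (p in panels) {
    ylim <- range(c(h[[p$col]], p$normal))
    graphics::plot(NA, xlim = range(h$date), ylim = ylim,
                   xlab = "visit date", ylab = p$lab,
                   main = sprintf("Patient %s - %s", patient, p$lab))
    graphics::rect(min(h$date) - 1e6, p$normal[1L], max(h$date) + 1e6,
                   p$normal[2L], col = "#d8eed8", border = NA)
    for (sd_ in unique(h$side)) {
      hh <- h[h$side == sd_, , drop = FALSE]
      graphics::lines(hh$date, hh[[p$col]], type = "b", pch = 19,
                      col = if (sd_ == "left") "#2c6fbb" else "#bb4b2c")
    }
    graphics::legend("topright", legend = unique(h$side), pch = 19,
                     col = ifelse(unique(h$side) == "left", "#2c6fbb",
                                  "#bb4b2c"), bty = "n")
  }
  invisible(outPng)
}
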