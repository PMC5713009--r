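#' Sigma-rule precision report for repeated measurements
#'
#' Applies the one-sigma / three-sigma rule to a series of repeated
#' measurements of the same quantity (e.g. five repeats of one index on one
#' foot): for approximately normal data about 68% of the values lie within
#' one standard deviation of the mean and 99.7% within three, so repeated
#' measurements of a stable quantity should essentially never leave the
#' three-sigma band. The standard deviation is the sample (n - 1) estimate;
#' "outside" is the strict inequality |v - mean| > k sd.
#'
#' @param values numeric vector of >= 2 finite repeated measurements.
#' @return A [PrecisionReport-class].
#' @examples
#' sigmaRuleReport(c(1, 1, 1, 1, 2))  # one value outside one sigma
#' @export
sigmaRuleReport <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("insufficient repeats: need at least 2 values")
  if (!all(is.finite(values))) stop("values must be finite")
  m <- mean(values)
  s <- stats::sd(values)
  dev <- abs(values - m)
  new("PrecisionReport", n = length(values), mean = m, sd = s,
      nOutside1Sigma = sum(dev > 1 * s), nOutside3Sigma = sum(dev > 3 * s),
      passes3Sigma = sum(dev > 3 * s) == 0L)
}

#' Pearson product-moment correlation
#'
#' Thin, argument-checked front end to [stats::cor()] for comparing two
#' measurement methods across subjects.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation coefficient in [-1, 1].
#' @examples
#' pearsonR(1:10, 2 * (1:10) + 1)  # 1
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant series")
  stats::cor(x, y, method = "pearson")
}

#' Agreement between two measurement methods
#'
#' Given the same index measured on the same feet by two methods (e.g. the
#' image pipeline vs digitalised ink-mat prints), reports the Pearson
#' correlation of the raw values and the percentage of feet whose
#' five-group classification differs between the methods.
#'
#' @param a,b paired numeric vectors, one value per foot, same subjects in
#'   the same order.
#' @param index which index the values are: \code{"staheli"}, \code{"csi"}
#'   (percent scale) or \code{"clarke"}.
#' @param table a [ClassificationTable-class].
#' @return list with elements \code{pearsonR} and
#'   \code{groupDisagreementPct}.
#' @export
methodAgreement <- function(a, b, index = c("staheli", "csi", "clarke"),
                            table = defaultClassificationTable()) {
  index <- match.arg(index)
  r <- pearsonR(a, b)
  ga <- classifyValue(a, index, table)
  gb <- classifyValue(b, index, table)
  list(pearsonR = r, groupDisagreementPct = 100 * mean(ga != gb))
}

#' Read a repeated-measures table from CSV
#'
#' Expects columns subject, side, index, repeat, value (extra columns are
#' kept). Lines starting with \code{#} are skipped.
#'
#' @param path CSV file path.
#' @return data.frame with one row per repeat.
#' @export
readRepeatedMeasures <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  # read.csv mangles the reserved word "repeat" to "repeat."
  names(df)[names(df) == "repeat."] <- "repeat"
  need <- c("subject", "side", "index", "repeat", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("repeated-measures CSV lacks columns: ",
         paste(miss, collapse = ", "))
  df
}

#' Per-series precision summary of a repeated-measures table
#'
#' Applies [sigmaRuleReport()] to every (subject, side, index) series.
#'
#' @param measures data.frame with columns subject, side, index, value (as
#'   from [readRepeatedMeasures()] or [generateCohort()]).
#' @return data.frame with one row per series: n, mean, sd, counts outside
#'   one and three sigma and the three-sigma pass flag.
#' @export
precisionSummary <- function(measures) {
  need <- c("subject", "side", "index", "value")
  miss <- setdiff(need, names(measures))
  if (length(miss))
    stop("measures table lacks columns: ", paste(miss, collapse = ", "))
  key <- interaction(measures$subject, measures$side, measures$index,
                     drop = TRUE)
  rows <- lapply(split(measures, key), function(g) {
    rep <- sigmaRuleReport(g$value)
    data.frame(subject = g$subject[1L], side = g$side[1L],
               index = g$index[1L], n = rep@n, mean = rep@mean,
               sd = rep@sd, nOutside1Sigma = rep@nOutside1Sigma,
               nOutside3Sigma = rep@nOutside3Sigma,
               passes3Sigma = rep@passes3Sigma)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$subject, out$side, out$index), , drop = FALSE]
}

#' Write a precision summary as CSV or JSON
#'
#' @param summary data.frame from [precisionSummary()].
#' @param path output file; format inferred from the extension unless
#'   \code{format} is given.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writePrecisionReport <- function(summary, path,
                                 format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  if (format == "csv") {
    utils::write.csv(summary, path, row.names = FALSE)
  } else {
    writeLines(jsonlite::toJSON(summary, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
  }
  invisible(path)
}
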