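#' Daily degree-days by single triangulation
#'
#' Approximates the diurnal temperature curve as a triangle between tmin and
#' tmax and returns the area above the lower developmental threshold
#' \code{tLower} (default 5.5 degC):
#' \itemize{
#'   \item tmax <= tLower: 0
#'   \item tmin >= tLower: (tmax + tmin)/2 - tLower
#'   \item otherwise:     (tmax - tLower)^2 / (2 (tmax - tmin))
#' }
#' With an upper threshold \code{tUpper} set, the triangle area above
#' \code{tUpper} is subtracted by the same geometry (no upper threshold by
#' default).
#'
#' @param tmin,tmax numeric vectors of daily minimum/maximum temperature
#'   (degC); \code{tmax >= tmin} required.
#' @param tLower lower developmental threshold (default 5.5).
#' @param tUpper optional upper developmental threshold.
#' @return numeric vector of daily degree-days (degC-day), all >= 0.
#' @examples
#' singleTriangulation(10, 20)        # 9.5
#' singleTriangulation(0, 11)         # 1.375
#' @export
singleTriangulation <- function(tmin, tmax, tLower = 5.5, tUpper = NULL) {
  bad <- which(tmax < tmin)
  if (length(bad))
    stop("tmax < tmin on day(s): ", paste(head(bad, 5), collapse = ", "))
  area <- function(thr) {
    ifelse(tmax <= thr, 0,
           ifelse(tmin >= thr, (tmax + tmin) / 2 - thr,
                  (tmax - thr)^2 / (2 * (tmax - tmin))))
  }
  dd <- area(tLower)
  if (!is.null(tUpper)) dd <- dd - area(tUpper)
  pmax(dd, 0)
}

#' Calibrate station temperatures against on-site loggers
#'
#' Computes the median logger-minus-station difference over paired days,
#' separately for daily highs and lows, and applies each as an additive
#' correction to the full station series (from 1 January onward).  A
#' Wilcoxon-Mann-Whitney test of logger vs station values is reported for
#' highs and lows; \code{paired = TRUE} switches to the signed-rank variant.
#'
#' @param logger,station data.frames with columns \code{date}, \code{tmin},
#'   \code{tmax} for one location.
#' @param paired use the signed-rank (paired) test instead of the unpaired
#'   rank-sum test (default FALSE).
#' @return list of class \code{"CalibrationResult"}: \code{medianHigh},
#'   \code{medianLow}, \code{testHigh}, \code{testLow} (statistic and p),
#'   \code{nPaired}, \code{corrected} (the corrected station series),
#'   \code{applied} flag.
#' @export
calibrateTemperature <- function(logger, station, paired = FALSE) {
  m <- merge(logger, station, by = "date", suffixes = c(".lg", ".st"))
  if (!nrow(m)) stop("no overlapping days between logger and station")
  dHi <- m$tmax.lg - m$tmax.st
  dLo <- m$tmin.lg - m$tmin.st
  medHi <- median(dHi); medLo <- median(dLo)
  wt <- function(a, b) {
    t <- suppressWarnings(
      if (paired) wilcox.test(a, b, paired = TRUE, exact = FALSE)
      else wilcox.test(a, b, exact = FALSE))
    list(statistic = unname(t$statistic), p = t$p.value)
  }
  corrected <- station
  corrected$tmax <- station$tmax + medHi
  corrected$tmin <- station$tmin + medLo
  corrected$tmax <- pmax(corrected$tmax, corrected$tmin)
  out <- list(medianHigh = medHi, medianLow = medLo,
              testHigh = wt(m$tmax.lg, m$tmax.st),
              testLow = wt(m$tmin.lg, m$tmin.st),
              nPaired = nrow(m), corrected = corrected, applied = TRUE)
  class(out) <- "CalibrationResult"
  out
}

#' @export
print.CalibrationResult <- function(x, ...) {
  cat(sprintf("CalibrationResult: median highs %+.2f, lows %+.2f over %d paired days\n",
              x$medianHigh, x$medianLow, x$nPaired))
  invisible(x)
}

#' Accumulate degree-days from 1 January
#'
#' Computes daily single-triangulation degree-days and their cumulative sum
#' per location.  Missing calendar days inside the series are filled by
#' linear interpolation of tmin and tmax, with the interpolated-day count
#' reported as an attribute.
#'
#' @param temperature data.frame: location, date, tmin, tmax (one source).
#' @param tLower,tUpper thresholds passed to [singleTriangulation()].
#' @return DegreeDayTable data.frame: location, date, dd, cumdd (cumulative
#'   is non-decreasing); attribute \code{"interpolated"} counts filled days.
#' @export
accumulateDegreeDays <- function(temperature, tLower = 5.5, tUpper = NULL) {
  out <- lapply(split(temperature, temperature$location), function(d) {
    d <- d[order(d$date), ]
    full <- seq(min(d$date), max(d$date), by = "day")
    nMiss <- length(full) - nrow(d)
    if (nMiss > 0) {
      tmin <- stats::approx(as.numeric(d$date), d$tmin, as.numeric(full))$y
      tmax <- stats::approx(as.numeric(d$date), d$tmax, as.numeric(full))$y
      d <- data.frame(location = d$location[1], date = full,
                      tmin = tmin, tmax = tmax)
    }
    dd <- singleTriangulation(d$tmin, d$tmax, tLower, tUpper)
    r <- data.frame(location = d$location[1], date = d$date, dd = dd,
                    cumdd = cumsum(dd))
    attr(r, "interpolated") <- nMiss
    r
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "interpolated") <- sum(vapply(out, attr, 0L, "interpolated"))
  res
}

#' Accumulated degree-days at each individual's collection date
#'
#' Joins the degree-day table on (location, collection date); the value for
#' a collection on day d is the cumulative sum through day d inclusive
#' (configurable to exclusive).  Dates outside a location's series are an
#' error.  Degree-day tables spanning multiple years should be accumulated
#' per year before joining.
#'
#' @param ddTable DegreeDayTable from [accumulateDegreeDays()] (one year).
#' @param samples SampleTable with columns location, date.
#' @param inclusive include the collection day itself (default TRUE).
#' @return \code{samples} with an added \code{dd} column.
#' @export
ddAtCollection <- function(ddTable, samples, inclusive = TRUE) {
  key <- paste(ddTable$location, ddTable$date)
  lookup <- setNames(ddTable$cumdd, key)
  qdate <- if (inclusive) samples$date else samples$date - 1
  v <- lookup[paste(samples$location, qdate)]
  if (any(is.na(v)))
    stop("collection date(s) outside the degree-day series for: ",
         paste(head(unique(samples$location[is.na(v)]), 5), collapse = ", "))
  samples$dd <- unname(v)
  samples
}
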