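#' Build a collection grid of per-interval taxon counts
#'
#' Tabulates genotyped individuals with parental taxon labels into the
#' (location, year, interval) grid.  F1 hybrids (and any other non-parental
#' label) contribute to neither taxon.  Intervals with zero counts are kept
#' in the grid.
#'
#' @param samples SampleTable data.frame (id, location, year, interval, date).
#' @param labels named character vector of taxon labels per individual id;
#'   the two parental labels are taken from \code{taxa}.
#' @param taxa character(2), the parental taxon labels (default the two
#'   most frequent non-hybrid labels).
#' @return data.frame of class \code{"CollectionGrid"}: location, year,
#'   interval, date, nTaxon1, nTaxon2, with the taxa as an attribute.
#' @export
buildGrid <- function(samples, labels, taxa = NULL) {
  if (any(is.na(samples$interval))) stop("sample(s) with missing interval")
  lab <- labels[samples$id]
  if (is.null(taxa)) {
    tt <- sort(table(lab[lab %in% c("P1", "P2") | !lab %in%
                           c("F1", "F2", "BC1", "BC2", "ambiguous", "undefined")]),
               decreasing = TRUE)
    taxa <- names(tt)[1:2]
  }
  key <- unique(samples[, c("location", "year", "interval", "date")])
  key <- key[order(key$location, key$year, key$interval), ]
  cnt <- function(taxon) {
    sel <- !is.na(lab) & lab == taxon
    t <- table(paste(samples$location, samples$year, samples$interval)[sel])
    as.integer(t[paste(key$location, key$year, key$interval)])
  }
  g <- data.frame(key, nTaxon1 = cnt(taxa[1]), nTaxon2 = cnt(taxa[2]))
  g$nTaxon1[is.na(g$nTaxon1)] <- 0L
  g$nTaxon2[is.na(g$nTaxon2)] <- 0L
  attr(g, "taxa") <- taxa
  class(g) <- c("CollectionGrid", "data.frame")
  g
}

sympatricLocations <- function(grid) {
  byLoc <- split(grid, grid$location)
  names(byLoc)[vapply(byLoc, function(d)
    any(d$nTaxon1 > 0) && any(d$nTaxon2 > 0), TRUE)]
}

overlapReport <- function(index, grain, value, components, num, den) {
  out <- list(index = index, grain = grain, value = value,
              components = components, numerator = num, denominator = den)
  class(out) <- "OverlapReport"
  out
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat(sprintf("OverlapReport [%s, %s]: %.3f (%.1f%%)\n",
              x$index, x$grain, x$value, 100 * x$value))
  invisible(x)
}

#' Presence-based co-occurrence index
#'
#' The number of collection periods in which both taxa were present divided
#' by the number of periods in which either was present.  At grain
#' \code{"by_location"} the index is computed per sympatric location and
#' unweighted-averaged across locations; at grain \code{"pooled"} presence
#' is unioned across locations per (year, interval) before taking the
#' ratio.  Years are never merged with each other.  Intervals where neither
#' taxon occurs never enter the denominator.
#'
#' @param grid a CollectionGrid from [buildGrid()].
#' @param grain "by_location" or "pooled".
#' @param locations optional character vector restricting the locations
#'   considered (default: all sympatric locations for "by_location", all
#'   locations for "pooled").
#' @param weighted if TRUE, the by-location average weights locations by
#'   their number of occupied intervals (default FALSE, unweighted).
#' @return an OverlapReport; value NA (flagged) if the denominator is 0.
#' @export
presenceIndex <- function(grid, grain = c("by_location", "pooled"),
                          locations = NULL, weighted = FALSE) {
  grain <- match.arg(grain)
  ratio <- function(d) {
    both <- sum(d$nTaxon1 > 0 & d$nTaxon2 > 0)
    either <- sum(d$nTaxon1 > 0 | d$nTaxon2 > 0)
    c(both, either)
  }
  if (grain == "by_location") {
    locs <- if (is.null(locations)) sympatricLocations(grid) else locations
    if (!length(locs)) stop("no sympatric locations")
    comp <- vapply(locs, function(l) {
      r <- ratio(grid[grid$location == l, ])
      if (r[2] == 0) NA_real_ else r[1] / r[2]
    }, 0)
    w <- if (weighted)
      vapply(locs, function(l) sum(grid$location == l &
                                     (grid$nTaxon1 > 0 | grid$nTaxon2 > 0)), 0)
    else rep(1, length(locs))
    val <- sum(comp * w, na.rm = TRUE) / sum(w[!is.na(comp)])
    overlapReport("presence", grain, val, setNames(comp, locs), NA, NA)
  } else {
    g <- if (is.null(locations)) grid else grid[grid$location %in% locations, ]
    agg <- stats::aggregate(cbind(nTaxon1, nTaxon2) ~ year + interval,
                            data = g, FUN = sum)
    r <- ratio(agg)
    val <- if (r[2] == 0) NA_real_ else r[1] / r[2]
    if (r[2] == 0) warning("denominator 0: no interval with either taxon")
    overlapReport("presence", grain, val, NULL, r[1], r[2])
  }
}

#' Abundance-based co-occurrence index
#'
#' The number of individuals of both taxa collected in co-occurrence
#' intervals (intervals where both taxa have positive counts at the stated
#' grain) divided by all parental individuals at that grain.  With
#' \code{numerator = "minority"}, only the scarcer taxon's individuals in
#' each co-occurrence interval are counted instead.
#'
#' @inheritParams presenceIndex
#' @param numerator "both" (default; both taxa's individuals in shared
#'   intervals) or "minority".
#' @return an OverlapReport.
#' @export
abundanceIndex <- function(grid, grain = c("by_location", "pooled"),
                           locations = NULL, numerator = c("both", "minority"),
                           weighted = FALSE) {
  grain <- match.arg(grain)
  numerator <- match.arg(numerator)
  ratio <- function(d) {
    shared <- d$nTaxon1 > 0 & d$nTaxon2 > 0
    num <- if (numerator == "both") sum(d$nTaxon1[shared] + d$nTaxon2[shared])
           else sum(pmin(d$nTaxon1[shared], d$nTaxon2[shared]))
    den <- sum(d$nTaxon1 + d$nTaxon2)
    c(num, den)
  }
  if (grain == "by_location") {
    locs <- if (is.null(locations)) sympatricLocations(grid) else locations
    if (!length(locs)) stop("no sympatric locations")
    comp <- vapply(locs, function(l) {
      r <- ratio(grid[grid$location == l, ])
      if (r[2] == 0) NA_real_ else r[1] / r[2]
    }, 0)
    w <- if (weighted)
      vapply(locs, function(l)
        sum(grid$nTaxon1[grid$location == l] + grid$nTaxon2[grid$location == l]), 0)
    else rep(1, length(locs))
    val <- sum(comp * w, na.rm = TRUE) / sum(w[!is.na(comp)])
    overlapReport("abundance", grain, val, setNames(comp, locs), NA, NA)
  } else {
    g <- if (is.null(locations)) grid else grid[grid$location %in% locations, ]
    agg <- stats::aggregate(cbind(nTaxon1, nTaxon2) ~ year + interval,
                            data = g, FUN = sum)
    r <- ratio(agg)
    val <- if (r[2] == 0) NA_real_ else r[1] / r[2]
    overlapReport("abundance", grain, val, NULL, r[1], r[2])
  }
}

## Mann-Whitney U from midranks (U for the first sample), with tie-corrected
## normal-approximation p and both effect-size conventions
mannWhitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (U1 - n1 * n2 / 2) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  list(U1 = U1, U2 = U2, z = z, p = p,
       rRankBiserial = abs(1 - 2 * U1 / (n1 * n2)),
       rZ = abs(z) / sqrt(N))
}

#' Compare flight timing between two taxa
#'
#' Per-taxon median and quartiles of the chosen flight value (collection
#' date or accumulated degree-days at collection), with a
#' Wilcoxon-Mann-Whitney comparison: the U statistic with midrank tie
#' handling (both orientations U1 and U2 reported), tie-corrected
#' normal-approximation p, and the effect size r under both conventions
#' (rank-biserial |1 - 2U/(n1 n2)| and |Z|/sqrt(N)), labelled.
#'
#' @param samples SampleTable with a \code{date} column and, when
#'   \code{value = "degree_days"}, a \code{dd} column (see
#'   [ddAtCollection()]).
#' @param labels named character vector of taxon labels per id.
#' @param taxa character(2): the two labels to compare.
#' @param value "date" or "degree_days".
#' @return list: per-taxon \code{summary} (n, median, q25, q75),
#'   \code{U1}, \code{U2}, \code{z}, \code{p}, \code{rRankBiserial},
#'   \code{rZ}.
#' @export
flightSummary <- function(samples, labels, taxa,
                          value = c("date", "degree_days")) {
  value <- match.arg(value)
  lab <- labels[samples$id]
  v <- if (value == "date") as.numeric(samples$date) else samples$dd
  if (value == "degree_days" && is.null(samples$dd))
    stop("samples need a 'dd' column; see ddAtCollection()")
  x <- v[!is.na(lab) & lab == taxa[1]]
  y <- v[!is.na(lab) & lab == taxa[2]]
  if (!length(x) || !length(y)) stop("a taxon group is empty")
  mw <- mannWhitney(x, y)
  summ <- function(v) c(n = length(v), median = median(v),
                        q25 = unname(quantile(v, .25)),
                        q75 = unname(quantile(v, .75)))
  tab <- rbind(summ(x), summ(y))
  rownames(tab) <- taxa
  c(list(summary = tab, taxa = taxa, value = value), mw)
}
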