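#' Simulation configuration for a two-taxon trapping study
#'
#' Bundles every parameter of the synthetic study generator: genotype
#' divergence, cross composition, degree-day phenology, trap design and
#' temperature structure.  Defaults emulate a two-year pheromone-trap survey
#' of two spruce budworm taxa at ten locations: taxon 1 univoltine and
#' earlier-flying, taxon 2 biennial (adults mainly in its parity year) and
#' later-flying, divergence F_ST 0.34 over ~2,800 SNPs, rare F1 hybrids, and
#' 10-day collection intervals.
#'
#' @param nPop1,nPop2 pure parental individual counts (defaults 102, 153).
#' @param nF1,nF2,nBc1,nBc2 hybrid-class counts (defaults 5, 0, 0, 0).
#' @param nLoci number of biallelic loci (default 2831).
#' @param nScaffolds number of synthetic scaffolds loci are placed on.
#' @param fstTarget between-taxon divergence parameter in [0,1] (default 0.34).
#' @param ancestralMafRange interval in (0, 0.5] for ancestral minor-allele
#'   frequencies (default c(0.1, 0.5)).
#' @param missingRate fraction of calls set missing (default 0.0279).
#' @param seed integer; fully determines all outputs.
#' @param locations data.frame describing trap locations: \code{id},
#'   \code{tempOffsetC} (latitude-like shift of the local temperature
#'   climate), \code{loggerOffsetC} (fixed logger-minus-station offset),
#'   \code{sp1}, \code{sp2} (logical residency flags), \code{parityYear}
#'   (high-abundance year of the biennial taxon).  Default: ten locations
#'   a-j, a-c taxon-2 only, d-i sympatric, j taxon-1 dominated.
#' @param ddThresholdSp1,ddThresholdSp2 adult-emergence thresholds in
#'   accumulated degree-days above 5.5 degC (defaults 600, 830; roughly a
#'   three-week flight offset under the default climate).
#' @param ddNoiseSd individual Gaussian spread of the threshold in
#'   degC-days (default 60, roughly a 5-day emergence SD under the default
#'   climate, so each location's flight period spans 2-3 collection
#'   intervals).
#' @param hybridThresholdFrac position of the hybrid threshold between the
#'   parental thresholds; 0.5 = midpoint (default).
#' @param offYearFraction fraction of biennial individuals flying outside
#'   their parity year (default 0.05).
#' @param years survey years (default 2017:2018).
#' @param seasonStart,seasonEnd trap season as "MM-DD" (defaults "06-01",
#'   "09-03").
#' @param intervalLenDays trap collection interval length (default 10).
#' @param trapCap,trapFloor genotyping subsample cap and floor per interval
#'   (defaults 10, 3).
#' @param tempNoiseSd,loggerNoiseSd daily temperature noise SDs in degC.
#' @return a named list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nPop1 = 102L, nPop2 = 153L, nF1 = 5L, nF2 = 0L,
                      nBc1 = 0L, nBc2 = 0L, nLoci = 2831L, nScaffolds = 400L,
                      fstTarget = 0.34, ancestralMafRange = c(0.1, 0.5),
                      missingRate = 0.0279, seed = 1L,
                      locations = defaultLocations(),
                      ddThresholdSp1 = 600, ddThresholdSp2 = 830,
                      ddNoiseSd = 60, hybridThresholdFrac = 0.5,
                      offYearFraction = 0.05, years = 2017:2018,
                      seasonStart = "06-01", seasonEnd = "09-03",
                      intervalLenDays = 10L, trapCap = 10L, trapFloor = 3L,
                      tempNoiseSd = 2, loggerNoiseSd = 0.3) {
  cfg <- list(nPop1 = as.integer(nPop1), nPop2 = as.integer(nPop2),
              nF1 = as.integer(nF1), nF2 = as.integer(nF2),
              nBc1 = as.integer(nBc1), nBc2 = as.integer(nBc2),
              nLoci = as.integer(nLoci), nScaffolds = as.integer(nScaffolds),
              fstTarget = fstTarget, ancestralMafRange = ancestralMafRange,
              missingRate = missingRate, seed = as.integer(seed),
              locations = locations, ddThresholdSp1 = ddThresholdSp1,
              ddThresholdSp2 = ddThresholdSp2, ddNoiseSd = ddNoiseSd,
              hybridThresholdFrac = hybridThresholdFrac,
              offYearFraction = offYearFraction, years = as.integer(years),
              seasonStart = seasonStart, seasonEnd = seasonEnd,
              intervalLenDays = as.integer(intervalLenDays),
              trapCap = as.integer(trapCap), trapFloor = as.integer(trapFloor),
              tempNoiseSd = tempNoiseSd, loggerNoiseSd = loggerNoiseSd)
  counts <- unlist(cfg[c("nPop1", "nPop2", "nF1", "nF2", "nBc1", "nBc2")])
  if (any(counts < 0)) stop("class counts must be >= 0")
  if (fstTarget < 0 || fstTarget > 1) stop("fstTarget must lie in [0,1]")
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must lie in [0,1)")
  if (ancestralMafRange[1] <= 0 || ancestralMafRange[2] > 0.5 ||
      ancestralMafRange[1] > ancestralMafRange[2])
    stop("ancestralMafRange must be an interval within (0, 0.5]")
  class(cfg) <- "SimConfig"
  cfg
}

#' @rdname simConfig
#' @export
defaultLocations <- function() {
  data.frame(
    id = letters[1:10],
    tempOffsetC = round(seq(4, -4, length.out = 10), 2),
    loggerOffsetC = c(0.6, 1.1, 1.6, 0.9, 1.4, 1.9, 0.7, 1.2, 1.7, 1.0),
    sp1 = c(FALSE, FALSE, FALSE, rep(TRUE, 7)),
    sp2 = c(rep(TRUE, 9), TRUE),
    parityYear = 2018L,
    stringsAsFactors = FALSE)
}

## deterministic sub-seeds, kept well below 2^31
subSeed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 2000000011L

#' Draw divergent per-population allele frequencies
#'
#' Balding-Nichols model: for each locus an ancestral frequency is drawn
#' uniformly on \code{ancestralMafRange}, and each population's frequency is
#' drawn from \code{Beta(p(1-F)/F, (1-p)(1-F)/F)}, which has mean p and
#' F_ST-like variance parameter F.  \code{fstTarget = 0} returns identical
#' frequencies; \code{fstTarget = 1} fixes each population at 0 or 1.
#'
#' @param nLoci number of loci.
#' @param fstTarget divergence parameter in [0,1].
#' @param ancestralMafRange interval in (0, 0.5].
#' @param seed integer.
#' @return data.frame with columns \code{anc}, \code{p1}, \code{p2}.
#' @export
simulateAlleleFreqs <- function(nLoci, fstTarget, ancestralMafRange = c(0.1, 0.5),
                                seed = 1L) {
  if (fstTarget < 0 || fstTarget > 1) stop("fstTarget must lie in [0,1]")
  if (ancestralMafRange[1] <= 0 || ancestralMafRange[2] > 0.5)
    stop("ancestralMafRange must lie within (0, 0.5]")
  set.seed(subSeed(seed, 1L))
  anc <- runif(nLoci, ancestralMafRange[1], ancestralMafRange[2])
  drawPop <- function() {
    if (fstTarget == 0) return(anc)
    if (fstTarget == 1) return(as.numeric(rbinom(nLoci, 1L, anc)))
    a <- anc * (1 - fstTarget) / fstTarget
    b <- (1 - anc) * (1 - fstTarget) / fstTarget
    rbeta(nLoci, a, b)
  }
  data.frame(anc = anc, p1 = drawPop(), p2 = drawPop())
}

## one haploid gamete pool draw per locus for n individuals: matrix loci x n
gametes <- function(p, n) {
  matrix(rbinom(length(p) * n, 1L, rep(p, n)), nrow = length(p))
}

#' Simulate genotypes for parental and hybrid classes
#'
#' Parental genotypes are Hardy-Weinberg draws within each population.  F1 =
#' one gamete from each parental pool; F2 = two F1 gametes (allele
#' probability (p1+p2)/2 per gamete); BC1/BC2 = one F1 gamete plus one
#' parental gamete.  Missing calls are set independently at
#' \code{missingRate}.  Loci are placed on synthetic scaffolds at uniform
#' random positions so distance-based thinning is exercised downstream.
#'
#' @param freqs data.frame from [simulateAlleleFreqs()].
#' @param counts named vector/list with nPop1, nPop2, nF1, nF2, nBc1, nBc2.
#' @param missingRate fraction of calls set to NA.
#' @param seed integer.
#' @param nScaffolds scaffolds to scatter loci over.
#' @return list with \code{genotypes} (a \linkS4class{GenotypeMatrix}) and
#'   \code{truth} (data.frame id, class).
#' @export
simulateGenotypes <- function(freqs, counts, missingRate = 0, seed = 1L,
                              nScaffolds = 400L) {
  stopifnot(all(freqs$p1 >= 0 & freqs$p1 <= 1, freqs$p2 >= 0 & freqs$p2 <= 1))
  set.seed(subSeed(seed, 2L))
  n <- lapply(counts[c("nPop1", "nPop2", "nF1", "nF2", "nBc1", "nBc2")],
              as.integer)
  L <- nrow(freqs)
  p1 <- freqs$p1; p2 <- freqs$p2; pf1 <- (p1 + p2) / 2
  blocks <- list(
    P1  = if (n$nPop1) gametes(p1, n$nPop1) + gametes(p1, n$nPop1),
    P2  = if (n$nPop2) gametes(p2, n$nPop2) + gametes(p2, n$nPop2),
    F1  = if (n$nF1)   gametes(p1, n$nF1) + gametes(p2, n$nF1),
    F2  = if (n$nF2)   gametes(pf1, n$nF2) + gametes(pf1, n$nF2),
    BC1 = if (n$nBc1)  gametes(pf1, n$nBc1) + gametes(p1, n$nBc1),
    BC2 = if (n$nBc2)  gametes(pf1, n$nBc2) + gametes(p2, n$nBc2))
  blocks <- Filter(Negate(is.null), blocks)
  dos <- do.call(cbind, blocks)
  classes <- rep(names(blocks), vapply(blocks, ncol, 1L))
  ids <- sprintf("%s_%03d", classes, unlist(lapply(blocks, function(b) seq_len(ncol(b)))))
  colnames(dos) <- ids
  if (missingRate > 0)
    dos[matrix(runif(length(dos)) < missingRate, nrow(dos))] <- NA
  scaf <- sprintf("scaffold%03d", sample.int(nScaffolds, L, replace = TRUE))
  pos <- sample.int(2000000L, L, replace = TRUE)
  o <- order(scaf, pos)
  loci <- data.frame(scaffold = scaf[o], pos = pos[o],
                     ref = "A", alt = "T")
  gm <- GenotypeMatrix(dos[o, , drop = FALSE], loci)
  list(genotypes = gm,
       truth = data.frame(id = ids, class = classes, stringsAsFactors = FALSE))
}

#' Simulate daily station and logger temperature series
#'
#' Daily mean temperature follows an annual sinusoid (peak in mid-July)
#' shifted by the location's climate offset, plus AR(1) anomalies; the
#' diurnal range splits the mean into tmin/tmax.  The logger series equals
#' the station series plus a fixed per-location offset and independent
#' observation noise; tmax is clamped to stay >= tmin.
#'
#' @param locationId location identifier.
#' @param year calendar year; the series covers 1 January through
#'   \code{year-seasonEnd}.
#' @param tempOffsetC climate offset of the location in degC.
#' @param loggerOffsetC fixed logger-minus-station offset in degC.
#' @param seed integer.
#' @param seasonEnd "MM-DD" end of coverage.
#' @param noiseSd SD of daily AR(1) anomalies (degC); 0 gives a pure sinusoid.
#' @param loggerNoiseSd SD of logger observation noise (degC).
#' @return data.frame: location, date, tmin, tmax, source ("station"/"logger").
#' @export
simulateTemperature <- function(locationId, year, tempOffsetC = 0,
                                loggerOffsetC = 0, seed = 1L,
                                seasonEnd = "09-03", noiseSd = 2,
                                loggerNoiseSd = 0.3) {
  set.seed(subSeed(seed, 3L + match(locationId, letters, nomatch = 0L) +
                     100L * (year %% 100L)))
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-%s", year, seasonEnd)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  m <- 2 + tempOffsetC + 16 * cos(2 * pi * (doy - 200) / 365.25)
  nd <- length(dates)
  e <- numeric(nd)
  if (noiseSd > 0) {
    innov <- rnorm(nd, 0, noiseSd)
    for (i in seq_len(nd)) e[i] <- if (i == 1) innov[1] else 0.7 * e[i - 1] + innov[i]
  }
  dr <- pmax(2, 10 + if (noiseSd > 0) rnorm(nd, 0, 2) else 0)
  stTmin <- m + e - dr / 2
  stTmax <- m + e + dr / 2
  lgTmin <- stTmin + loggerOffsetC +
    if (loggerNoiseSd > 0) rnorm(nd, 0, loggerNoiseSd) else 0
  lgTmax <- stTmax + loggerOffsetC +
    if (loggerNoiseSd > 0) rnorm(nd, 0, loggerNoiseSd) else 0
  lgTmax <- pmax(lgTmax, lgTmin)
  rbind(
    data.frame(location = locationId, date = dates, tmin = stTmin,
               tmax = stTmax, source = "station", stringsAsFactors = FALSE),
    data.frame(location = locationId, date = dates, tmin = lgTmin,
               tmax = lgTmax, source = "logger", stringsAsFactors = FALSE))
}

#' Simulate adult emergence dates from degree-day accumulation
#'
#' Each individual emerges on the first day its location's cumulative
#' degree-days (single triangulation above 5.5 degC from 1 January, computed
#' on the logger series = local truth) reach its taxon threshold plus
#' individual Gaussian noise.  Taxon-2 individuals fly only in their
#' location's parity year except an \code{offYearFraction}; hybrid classes
#' use a threshold interpolated between the parental thresholds.
#' Individuals whose threshold is never reached within the series are
#' returned with NA emergence (non-emerging).
#'
#' @param truth data.frame (id, class) from [simulateGenotypes()].
#' @param temperature data.frame from [simulateTemperature()] covering all
#'   locations/years, logger rows used.
#' @param config a [simConfig()] object.
#' @return data.frame: id, class, location, year, emergence (Date or NA).
#' @export
simulateEmergence <- function(truth, temperature, config) {
  set.seed(subSeed(config$seed, 11L))
  loc <- config$locations
  n <- nrow(truth)
  res <- truth
  biennial <- res$class == "P2"
  ## year: biennial fly in parity year except off-year fraction
  res$year <- sample(config$years, n, replace = TRUE)
  parity <- loc$parityYear[1]
  off <- runif(n) < config$offYearFraction
  offYears <- setdiff(config$years, parity)
  res$year[biennial] <- parity
  idx <- which(biennial & off)
  if (length(idx))
    res$year[idx] <- offYears[sample.int(length(offYears), length(idx),
                                         replace = TRUE)]
  ## location: uniform over locations where the taxon (or both, for hybrids)
  ## is resident
  pick <- function(ok) sample(loc$id[ok], 1L)
  res$location <- vapply(seq_len(n), function(i) {
    switch(res$class[i],
           P1 = pick(loc$sp1), P2 = pick(loc$sp2),
           pick(loc$sp1 & loc$sp2))
  }, "")
  ## per-individual degree-day threshold
  base <- c(P1 = config$ddThresholdSp1, P2 = config$ddThresholdSp2)
  hyb <- config$ddThresholdSp1 +
    config$hybridThresholdFrac * (config$ddThresholdSp2 - config$ddThresholdSp1)
  thr <- ifelse(res$class %in% c("P1", "P2"), base[res$class], hyb) +
    rnorm(n, 0, config$ddNoiseSd)
  ## cumulative degree-days per location-year on the logger (truth) series
  lg <- temperature[temperature$source == "logger", ]
  lg$year <- as.integer(format(lg$date, "%Y"))
  cums <- split(lg, list(lg$location, lg$year), drop = TRUE)
  cums <- lapply(cums, function(d) {
    d <- d[order(d$date), ]
    d$cum <- cumsum(singleTriangulation(d$tmin, d$tmax))
    d
  })
  res$emergence <- as.Date(NA)
  for (i in seq_len(n)) {
    key <- paste(res$location[i], res$year[i], sep = ".")
    d <- cums[[key]]
    if (is.null(d)) next
    hit <- which(d$cum >= thr[i])
    if (length(hit)) res$emergence[i] <- d$date[hit[1]]
  }
  res
}

#' Bin emergence into trap intervals and subsample for genotyping
#'
#' Emergence dates are binned into consecutive intervals of
#' \code{intervalLenDays} starting at the season start; the recorded
#' collection date of an individual is the trap-emptying date (interval
#' end).  Per location and interval, \code{min(available, trapCap)}
#' individuals are retained; the earliest and latest emergers of each
#' location-season are always retained.  Individuals emerging outside the
#' season are excluded and counted in \code{attr(result, "excluded")}.
#'
#' @param emergence data.frame from [simulateEmergence()].
#' @param config a [simConfig()] object.
#' @return SampleTable data.frame: id, location, year, interval, date,
#'   with the excluded count as an attribute.
#' @export
simulateTrapping <- function(emergence, config) {
  set.seed(subSeed(config$seed, 12L))
  em <- emergence[!is.na(emergence$emergence), ]
  excluded <- sum(is.na(emergence$emergence))
  out <- list()
  for (yr in config$years) {
    s0 <- as.Date(sprintf("%d-%s", yr, config$seasonStart))
    s1 <- as.Date(sprintf("%d-%s", yr, config$seasonEnd))
    nInt <- as.integer(ceiling(as.numeric(s1 - s0 + 1) / config$intervalLenDays))
    e <- em[em$year == yr, ]
    inSeason <- e$emergence >= s0 & e$emergence <= s1
    excluded <- excluded + sum(!inSeason)
    e <- e[inSeason, ]
    if (!nrow(e)) next
    e$interval <- as.integer(floor(as.numeric(e$emergence - s0) /
                                     config$intervalLenDays)) + 1L
    e$date <- s0 + e$interval * config$intervalLenDays - 1
    e$date <- pmin(e$date, s1)
    keep <- logical(nrow(e))
    for (l in unique(e$location)) {
      li <- which(e$location == l)
      ## season-extreme singletons always genotyped
      keep[li[which.min(e$emergence[li])]] <- TRUE
      keep[li[which.max(e$emergence[li])]] <- TRUE
      for (iv in unique(e$interval[li])) {
        ii <- li[e$interval[li] == iv]
        cap <- min(length(ii), config$trapCap)
        already <- ii[keep[ii]]
        extra <- setdiff(ii, already)
        nMore <- max(0L, cap - length(already))
        if (nMore > 0 && length(extra))
          keep[sample2(extra, min(nMore, length(extra)))] <- TRUE
      }
    }
    out[[as.character(yr)]] <- e[keep, c("id", "location", "year",
                                         "interval", "date")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

## sample() without the scalar-x surprise
sample2 <- function(x, size) if (length(x) == 1L) x[seq_len(size)] else sample(x, size)

#' Simulate per-location environmental variables
#'
#' Eight WorldClim-style bioclimatic summaries per location, driven by the
#' location's climate offset plus deterministic seeded noise, so
#' genotype-environment scans see spatially structured but locus-independent
#' predictors.
#'
#' @param locations location data.frame from a [simConfig()].
#' @param seed integer.
#' @return data.frame keyed by \code{location} with 8 variables.
#' @export
simulateEnvironment <- function(locations, seed = 1L) {
  set.seed(subSeed(seed, 13L))
  g <- locations$tempOffsetC
  n <- nrow(locations)
  noise <- function(s) rnorm(n, 0, s)
  data.frame(
    location = locations$id,
    meanAnnualTemp = 2 + g + noise(0.3),
    meanTempWarmestMonth = 18 + g + noise(0.4),
    meanTempColdestMonth = -14 + g + noise(0.5),
    meanTempWarmestQuarter = 15 + g + noise(0.4),
    meanTempColdestQuarter = -11 + g + noise(0.5),
    annualPrecip = 600 - 60 * g + noise(25),
    precipWarmestQuarter = 220 - 20 * g + noise(12),
    precipColdestQuarter = 110 - 10 * g + noise(8),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic trapping study
#'
#' Runs the whole generator: divergent allele frequencies, genotypes for
#' parental and hybrid classes, station/logger temperatures for every
#' location-year, degree-day-driven emergence, interval trapping with
#' genotyping subsampling, and per-location environmental variables.
#' All randomness is determined by \code{config$seed}.
#'
#' @param config a [simConfig()] object.
#' @return list: \code{genotypes} (\linkS4class{GenotypeMatrix}),
#'   \code{truth} (id, class, location, year, emergence), \code{samples}
#'   (SampleTable of genotyped individuals), \code{temperature},
#'   \code{environment}, \code{freqs}, \code{config}.
#' @examples
#' st <- simulateStudy(simConfig(nPop1 = 10, nPop2 = 10, nF1 = 2,
#'                               nLoci = 50, seed = 7))
#' st$genotypes
#' @export
simulateStudy <- function(config = simConfig()) {
  freqs <- simulateAlleleFreqs(config$nLoci, config$fstTarget,
                               config$ancestralMafRange, config$seed)
  g <- simulateGenotypes(freqs, config, config$missingRate, config$seed,
                         config$nScaffolds)
  temp <- do.call(rbind, lapply(config$years, function(yr) {
    do.call(rbind, lapply(seq_len(nrow(config$locations)), function(i) {
      l <- config$locations[i, ]
      simulateTemperature(l$id, yr, l$tempOffsetC, l$loggerOffsetC,
                          config$seed, config$seasonEnd,
                          config$tempNoiseSd, config$loggerNoiseSd)
    }))
  }))
  emerg <- simulateEmergence(g$truth, temp, config)
  samples <- simulateTrapping(emerg, config)
  env <- simulateEnvironment(config$locations, config$seed)
  list(genotypes = g$genotypes, truth = emerg, samples = samples,
       temperature = temp, environment = env, freqs = freqs, config = config)
}

#' Write a simulated study to plain-text files
#'
#' Writes the genotypes as VCF (GT only), the sample and truth tables as
#' TSV, and the temperature series and environment table as CSV/TSV under
#' \code{dir}.
#'
#' @param study result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.tsv"),
             temperature = file.path(dir, "temperature.csv"),
             environment = file.path(dir, "environment.tsv"))
  writeGenotypeVcf(study$genotypes, paths["vcf"])
  write.table(study$samples, paths["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(study$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  tmp <- study$temperature
  names(tmp)[names(tmp) %in% c("tmin", "tmax")] <- c("tmin_c", "tmax_c")
  write.table(tmp, paths["temperature"], sep = ",", quote = FALSE,
              row.names = FALSE)
  write.table(study$environment, paths["environment"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
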