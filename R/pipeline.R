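#' Run the full analysis pipeline on a (simulated or loaded) study
#'
#' Orchestrates every stage in order: SNP filtering; replicate admixture
#' fits with K selection and PCA; species assignment by membership
#' threshold; hybrid-category classification from >99%-membership reference
#' panels and the hybridization rate in the zone of sympatry; the
#' collection grid with both co-occurrence indices at both spatial grains;
#' degree-day accumulation (with logger/station calibration) and flight
#' comparisons on dates and degree-days; the Weir-Cockerham F-ST table and
#' a Bayesian outlier scan; and a latent-factor genotype-environment scan.
#' Thresholds default to the study's printed values: call rate 0.95, MAF
#' 0.10, 10 kb thinning, species membership 0.90, reference panels 0.99,
#' q-value 0.05, lower developmental threshold 5.5 degC.
#'
#' @param study list as produced by [simulateStudy()] (fields
#'   \code{genotypes}, \code{samples}, \code{temperature},
#'   \code{environment}).
#' @param speciesThreshold,panelThreshold,qThreshold,callRateMin,mafMin,
#'   thinBp,tLower analysis thresholds.
#' @param nSnpClassifier loci used by the hybrid classifier (default 400).
#' @param scanPreset chain preset for [bayescanScan()] (default "reduced").
#' @param outlierScan run the MCMC outlier scan stage (default TRUE; the
#'   Weir-Cockerham table is always computed).
#' @param geaK latent factor count (default: chosen k from the admixture
#'   K selection).
#' @param seed integer seed for all stochastic stages.
#' @param outDir optional directory; when set, tables are written as
#'   TSV/JSON and a \code{summary.json} bundle index.
#' @return a named list ("report bundle") with one entry per stage.  If a
#'   stage fails, the partial bundle is returned with a \code{failures}
#'   manifest naming the stage and the error.
#' @export
runAll <- function(study, speciesThreshold = 0.90, panelThreshold = 0.99,
                   qThreshold = 0.05, callRateMin = 0.95, mafMin = 0.10,
                   thinBp = 10000, tLower = 5.5, nSnpClassifier = 400,
                   scanPreset = "reduced", outlierScan = TRUE, geaK = NULL,
                   seed = 1L, outDir = NULL) {
  bundle <- list(config = list(speciesThreshold = speciesThreshold,
                               panelThreshold = panelThreshold,
                               qThreshold = qThreshold,
                               callRateMin = callRateMin, mafMin = mafMin,
                               thinBp = thinBp, tLower = tLower,
                               nSnpClassifier = nSnpClassifier,
                               scanPreset = scanPreset, seed = seed))
  currentStage <- "input"
  err <- tryCatch({
  for (f in c("genotypes", "samples", "temperature", "environment"))
    if (is.null(study[[f]])) stop("missing input: ", f)

  ## genotyped individuals only
  currentStage <- "filter"
  gm <- study$genotypes[, intersect(sampleIds(study$genotypes),
                                    study$samples$id)]
  gm <- filterVariants(gm, callRateMin, mafMin, thinBp)
  bundle$filter <- filterReport(gm)

  currentStage <- "ancestry"
  fits <- replicateAdmixture(gm, kMax = 3, nReplicates = 3, seed = seed)
  bundle$kSelection <- selectK(fits)
  fit2 <- averageAdmixture(fits[[2]])
  bundle$admixture <- fit2
  bundle$pca <- genoPca(gm, 2)

  ## anchor clusters on the two most extreme individuals
  anchors <- list(sp1 = rownames(fit2@Q)[which.max(fit2@Q[, 1])],
                  sp2 = rownames(fit2@Q)[which.max(fit2@Q[, 2])])
  species <- assignSpecies(fit2, speciesThreshold, anchors)
  bundle$species <- species

  currentStage <- "hybrids"
  panel1 <- names(species)[fit2@Q[, 1] > panelThreshold]
  panel2 <- names(species)[fit2@Q[, 2] > panelThreshold]
  sub <- subsetSnps(gm, "first_n", nSnpClassifier)
  model <- buildHybridModel(sub, panel1, panel2)
  post <- classifyHybrids(model, sub)
  bundle$hybrids <- post
  labels <- hybridLabels(post)
  symLoc <- study$config$locations$id[study$config$locations$sp1 &
                                        study$config$locations$sp2]
  inSym <- study$samples$location[match(names(labels), study$samples$id)] %in% symLoc
  bundle$hybridizationRate <- hybridizationRate(labels, keep = inSym)

  currentStage <- "phenology"
  ## taxon labels for phenology: parental classes only
  taxLab <- ifelse(labels %in% c("P1", "P2"), labels, NA)
  taxLab <- setNames(taxLab, names(labels))
  grid <- buildGrid(study$samples, taxLab, taxa = c("P1", "P2"))
  bundle$grid <- grid
  bundle$overlap <- list(
    presenceByLocation = presenceIndex(grid, "by_location"),
    presencePooled = presenceIndex(grid, "pooled", locations = symLoc),
    abundanceByLocation = abundanceIndex(grid, "by_location"),
    abundancePooled = abundanceIndex(grid, "pooled", locations = symLoc))

  currentStage <- "degreedays"
  ## temperature calibration per location, then degree-days per year
  temp <- study$temperature
  cal <- lapply(split(temp, temp$location), function(d) {
    calibrateTemperature(d[d$source == "logger", ],
                         d[d$source == "station", ])
  })
  bundle$calibration <- cal
  corrected <- do.call(rbind, lapply(cal, function(cl) cl$corrected))
  corrected$year <- as.integer(format(corrected$date, "%Y"))
  samples <- study$samples
  samples$dd <- NA_real_
  for (yr in unique(samples$year)) {
    ddt <- accumulateDegreeDays(corrected[corrected$year == yr, ], tLower)
    sel <- samples$year == yr
    samples$dd[sel] <- ddAtCollection(ddt, samples[sel, ])$dd
  }
  bundle$samplesDd <- samples
  bundle$flightDates <- flightSummary(samples, taxLab, c("P1", "P2"), "date")
  bundle$flightDegreeDays <- flightSummary(samples, taxLab, c("P1", "P2"),
                                           "degree_days")

  currentStage <- "selscan"
  ## divergence scans between the parental groups
  spGroups <- taxLab[!is.na(taxLab)]
  bundle$fst <- wcFst(gm, spGroups)
  if (outlierScan) {
    cnt <- alleleCounts(gm, spGroups)
    bundle$outliers <- bayescanScan(cnt, qThreshold = qThreshold, seed = seed,
                                    preset = scanPreset)
  }

  currentStage <- "gea"
  if (is.null(geaK)) geaK <- bundle$kSelection$chosenK
  bundle$gea <- geaScan(gm, study$environment, study$samples, K = geaK)
  NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(err))
    bundle$failures <- setNames(list(err), currentStage)

  if (!is.null(outDir)) writeBundle(bundle, outDir)
  bundle
}

## write the report bundle as TSV/JSON files plus a summary index
writeBundle <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wTsv <- function(d, f) write.table(d, file.path(outDir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  wJson <- function(x, f) jsonlite::write_json(
    x, file.path(outDir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$admixture)) {
    q <- membership(bundle$admixture)
    wTsv(data.frame(id = rownames(q), q, check.names = FALSE), "admixture_q.tsv")
  }
  if (!is.null(bundle$species))
    wTsv(data.frame(id = names(bundle$species), species = bundle$species),
         "species.tsv")
  if (!is.null(bundle$hybrids)) {
    hp <- hybridPosterior(bundle$hybrids)
    wTsv(data.frame(id = rownames(hp), hp, label = hybridLabels(bundle$hybrids),
                    nLoci = bundle$hybrids@nLociUsed), "hybrid_posteriors.tsv")
  }
  if (!is.null(bundle$grid)) wTsv(bundle$grid, "collection_grid.tsv")
  if (!is.null(bundle$outliers))
    wTsv(scanTable(bundle$outliers), "outlier_scan.tsv")
  if (!is.null(bundle$fst)) wTsv(bundle$fst$perLocus, "fst_per_locus.tsv")
  if (!is.null(bundle$gea)) wTsv(geaTable(bundle$gea), "gea_scan.tsv")
  if (!is.null(bundle$samplesDd)) wTsv(bundle$samplesDd, "samples_degree_days.tsv")
  if (!is.null(bundle$calibration))
    wJson(lapply(bundle$calibration, function(cl)
      list(medianHigh = cl$medianHigh, medianLow = cl$medianLow,
           pHigh = cl$testHigh$p, pLow = cl$testLow$p, nPaired = cl$nPaired)),
      "calibration.json")
  ov <- lapply(bundle$overlap, function(o)
    list(index = o$index, grain = o$grain, value = o$value))
  wJson(list(filter = bundle$filter,
             hybridizationRate = bundle$hybridizationRate[
               c("rate", "percent", "nF1", "denominator", "text")],
             overlap = ov,
             fstOverall = bundle$fst$overall,
             chosenK = bundle$kSelection$chosenK,
             failures = bundle$failures,
             config = bundle$config), "summary.json")
  invisible(outDir)
}
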