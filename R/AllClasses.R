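#' @import methods
#' @importFrom stats median quantile rbeta rbinom rnorm runif sd setNames
#'   complete.cases pchisq pnorm qchisq p.adjust wilcox.test lm.fit rgamma
#' @importFrom utils head read.table write.table
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @useDynLib phenopop, .registration = TRUE
NULL

#' GenotypeMatrix: biallelic SNP dosages with locus coordinates
#'
#' An individuals-by-loci container for biallelic SNP genotypes, stored as a
#' \linkS4class{RangedSummarizedExperiment} with a single \code{"dosage"}
#' assay (loci in rows, individuals in columns).  Dosage is the count of
#' alternate alleles, \code{0}, \code{1} or \code{2}; missing calls are
#' \code{NA}.  Locus coordinates (scaffold, 1-based position, ref and alt
#' alleles) live in \code{rowRanges}.
#'
#' @slot .Data inherited \code{RangedSummarizedExperiment} structure.
#' @seealso [GenotypeMatrix()], [readGenotypeVcf()], [filterVariants()]
#' @name GenotypeMatrix-class
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

validGenotypeMatrix <- function(object) {
  msg <- NULL
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  if (length(object) && any(GenomicRanges::start(SummarizedExperiment::rowRanges(object)) < 1))
    msg <- c(msg, "locus positions must be >= 1")
  if (is.null(colnames(object)))
    msg <- c(msg, "individual ids (colnames) are required")
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeMatrix", validGenotypeMatrix)

#' Construct a GenotypeMatrix
#'
#' @param dosage numeric/integer matrix, loci x individuals, values in
#'   \{0,1,2,NA\}.  Column names are individual ids.
#' @param loci data.frame with columns \code{scaffold}, \code{pos} (1-based),
#'   and optionally \code{ref}, \code{alt}; one row per locus.
#' @param sampleIds optional character vector of individual ids overriding
#'   \code{colnames(dosage)}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0, 1, 2, NA), 2, 2,
#'                             dimnames = list(NULL, c("a", "b"))),
#'                      loci = data.frame(scaffold = "s1", pos = c(100, 5000)))
#' nLoci(gm)
#' @export
GenotypeMatrix <- function(dosage, loci, sampleIds = NULL) {
  dosage <- as.matrix(dosage)
  if (!is.null(sampleIds)) colnames(dosage) <- sampleIds
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("ind", seq_len(ncol(dosage)))
  stopifnot(nrow(dosage) == nrow(loci))
  if (is.null(loci$ref)) loci$ref <- "A"
  if (is.null(loci$alt)) loci$alt <- "T"
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(loci$scaffold),
    ranges = IRanges::IRanges(start = as.integer(loci$pos), width = 1L),
    ref = as.character(loci$ref), alt = as.character(loci$alt))
  names(rr) <- rownames(dosage) <- paste0(loci$scaffold, ":", loci$pos)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = rr)
  new("GenotypeMatrix", se)
}

#' @describeIn GenotypeMatrix dosage matrix (loci x individuals)
#' @param x a GenotypeMatrix
#' @export
dosage <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn GenotypeMatrix number of loci
#' @export
nLoci <- function(x) nrow(x)

#' @describeIn GenotypeMatrix number of individuals
#' @export
nInd <- function(x) ncol(x)

#' @describeIn GenotypeMatrix individual ids
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn GenotypeMatrix locus table (scaffold, pos, ref, alt)
#' @export
lociTable <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(scaffold = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = rr$ref, alt = rr$alt,
             row.names = NULL, stringsAsFactors = FALSE)
}

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dosage(object)
  cat("GenotypeMatrix:", nrow(object), "loci x", ncol(object), "individuals\n")
  cat("  scaffolds:", length(unique(as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object))))),
      " missing:", sprintf("%.2f%%", 100 * mean(is.na(d))), "\n")
  fr <- S4Vectors::metadata(object)$filterReport
  if (!is.null(fr)) cat("  filtered:", fr$input, "->", fr$output, "loci\n")
})

#' AdmixtureFit: maximum-likelihood admixture model fit
#'
#' Result of [fitAdmixture()]: per-individual membership coefficients Q
#' (rows sum to 1), per-cluster allele frequencies P, and the binomial
#' log-likelihood trace of the EM run.
#'
#' @slot k integer cluster count.
#' @slot Q numeric matrix, individuals x k.
#' @slot P numeric matrix, k x loci, allele frequencies in [0,1].
#' @slot loglik numeric final log-likelihood.
#' @slot loglikTrace numeric per-iteration log-likelihoods.
#' @slot nIter integer iterations run.
#' @slot converged logical.
#' @slot seed integer seed used for initialisation.
#' @exportClass AdmixtureFit
setClass("AdmixtureFit", representation(
  k = "integer", Q = "matrix", P = "matrix", loglik = "numeric",
  loglikTrace = "numeric", nIter = "integer", converged = "logical",
  seed = "integer"))

setValidity("AdmixtureFit", function(object) {
  if (nrow(object@Q) && any(abs(rowSums(object@Q) - 1) > 1e-8))
    return("Q rows must sum to 1")
  if (length(object@P) && (min(object@P) < 0 || max(object@P) > 1))
    return("P entries must lie in [0,1]")
  TRUE
})

#' @describeIn AdmixtureFit membership coefficient matrix (individuals x k)
#' @param x an AdmixtureFit
#' @export
membership <- function(x) x@Q

#' @describeIn AdmixtureFit model log-likelihood
#' @export
logLik.AdmixtureFit <- function(object, ...) object@loglik

setMethod("show", "AdmixtureFit", function(object) {
  cat("AdmixtureFit: k =", object@k, ",", nrow(object@Q), "individuals,",
      ncol(object@P), "loci\n")
  cat("  loglik:", format(object@loglik), " iter:", object@nIter,
      " converged:", object@converged, "\n")
})

#' HybridModel: parental allele frequencies and hybrid-class mixing weights
#'
#' Built by [buildHybridModel()].  For each class (P1, P2, F1, F2, BC1, BC2)
#' the mixing vector (pi0, pi1, pi2) gives the probability that a genotype
#' carries 0, 1 or 2 alleles of parental-1 origin.
#'
#' @slot p1 numeric per-locus parental-1 allele frequencies (smoothed).
#' @slot p2 numeric per-locus parental-2 allele frequencies (smoothed).
#' @slot mixing numeric 6 x 3 matrix of ancestry-copy mixing proportions.
#' @slot smoothing numeric smoothing constant used.
#' @exportClass HybridModel
setClass("HybridModel", representation(
  p1 = "numeric", p2 = "numeric", mixing = "matrix", smoothing = "numeric"))

setValidity("HybridModel", function(object) {
  if (any(abs(rowSums(object@mixing) - 1) > 1e-12))
    return("each class mixing vector must sum to 1")
  if (any(object@p1 <= 0 | object@p1 >= 1 | object@p2 <= 0 | object@p2 >= 1))
    return("smoothed frequencies must lie strictly in (0,1)")
  TRUE
})

setMethod("show", "HybridModel", function(object) {
  cat("HybridModel:", length(object@p1), "loci, classes:",
      paste(rownames(object@mixing), collapse = " "), "\n")
})

#' HybridPosterior: per-individual posterior over hybrid categories
#'
#' @slot posterior numeric matrix, individuals x 6 classes, rows sum to 1.
#' @slot label character max-posterior class per individual.
#' @slot nLociUsed integer non-missing loci per individual.
#' @exportClass HybridPosterior
setClass("HybridPosterior", representation(
  posterior = "matrix", label = "character", nLociUsed = "integer"))

setValidity("HybridPosterior", function(object) {
  ok <- stats::complete.cases(object@posterior)
  if (any(abs(rowSums(object@posterior[ok, , drop = FALSE]) - 1) > 1e-8))
    return("posterior rows must sum to 1")
  TRUE
})

#' @describeIn HybridPosterior class labels per individual
#' @param x a HybridPosterior
#' @export
hybridLabels <- function(x) setNames(x@label, rownames(x@posterior))

#' @describeIn HybridPosterior posterior matrix
#' @export
hybridPosterior <- function(x) x@posterior

setMethod("show", "HybridPosterior", function(object) {
  cat("HybridPosterior:", nrow(object@posterior), "individuals\n")
  print(table(object@label))
})

#' OutlierScan: Bayesian F-ST outlier scan result
#'
#' @slot table data.frame per locus: posterior inclusion probability,
#'   posterior odds, q-value, alpha and F-ST estimates, decision.
#' @slot settings list of chain settings used.
#' @slot seed integer.
#' @slot diagnostics list (acceptance rates, warnings).
#' @exportClass OutlierScan
setClass("OutlierScan", representation(
  table = "data.frame", settings = "list", seed = "integer",
  diagnostics = "list"))

#' @describeIn OutlierScan per-locus scan table
#' @param x an OutlierScan
#' @export
scanTable <- function(x) x@table

#' @describeIn OutlierScan loci flagged at the q-value threshold
#' @param qMax q-value decision threshold
#' @export
outlierLoci <- function(x, qMax = 0.05) {
  x@table$locus[!is.na(x@table$q) & x@table$q <= qMax]
}

setMethod("show", "OutlierScan", function(object) {
  cat("OutlierScan:", nrow(object@table), "loci,",
      sum(object@table$decision, na.rm = TRUE), "outliers at q <=",
      object@settings$qThreshold, "\n")
})

#' GEAScan: latent-factor genotype-environment association scan
#'
#' @slot table data.frame per locus x variable: effect, z, calibrated p, q.
#' @slot K integer number of latent factors.
#' @slot lambda named numeric genomic-inflation factor per variable.
#' @slot variables character variables tested.
#' @exportClass GEAScan
setClass("GEAScan", representation(
  table = "data.frame", K = "integer", lambda = "numeric",
  variables = "character"))

#' @describeIn GEAScan per-locus association table
#' @param x a GEAScan
#' @export
geaTable <- function(x) x@table

setMethod("show", "GEAScan", function(object) {
  cat("GEAScan:", length(unique(object@table$locus)), "loci x",
      length(object@variables), "variables, K =", object@K, "\n")
  cat("  discoveries at q<=0.05:", sum(object@table$q <= 0.05, na.rm = TRUE), "\n")
})
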