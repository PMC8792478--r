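#' Per-locus and genome-wide Weir-Cockerham F-ST
#'
#' Computes the Weir-Cockerham (1984) variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) per locus, the per-locus ratio theta = a/(a+b+c), and the
#' genome-wide ratio-of-sums estimate sum(a)/sum(a+b+c).  Loci where any
#' group has zero called genotypes are undefined and excluded from the
#' sums; loci monomorphic in all groups have a+b+c = 0 and are flagged NaN.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param groups named character/factor vector of group labels per
#'   individual id (individuals with NA labels are dropped).
#' @return list: \code{perLocus} data.frame (locus, a, b, c, theta,
#'   defined), \code{overall} (ratio of sums), \code{meanTheta},
#'   \code{sdTheta} (mean and SD of per-locus theta across defined loci),
#'   \code{groups} (levels used).
#' @export
wcFst <- function(x, groups) {
  d <- dosage(x)
  groups <- groups[colnames(d)]
  keep <- !is.na(groups)
  d <- d[, keep, drop = FALSE]
  g <- factor(groups[keep])
  r <- nlevels(g)
  if (r < 2) stop("need >= 2 groups")
  idx <- split(seq_len(ncol(d)), g)
  L <- nrow(d)
  ## per group per locus: sample size (called individuals), allele freq,
  ## observed heterozygote frequency
  n <- p <- h <- matrix(0, L, r)
  for (j in seq_len(r)) {
    sub <- d[, idx[[j]], drop = FALSE]
    called <- !is.na(sub)
    n[, j] <- rowSums(called)
    p[, j] <- rowSums(sub, na.rm = TRUE) / (2 * pmax(n[, j], 1))
    h[, j] <- rowSums(sub == 1, na.rm = TRUE) / pmax(n[, j], 1)
  }
  defined <- rowSums(n == 0) == 0
  nbar <- rowSums(n) / r
  nc <- (r * nbar - rowSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(n * p) / (r * nbar)
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  a[!defined] <- b[!defined] <- cc[!defined] <- theta[!defined] <- NA
  tot <- a + b + cc
  overall <- sum(a[defined & tot != 0], na.rm = TRUE) /
    sum(tot[defined & tot != 0], na.rm = TRUE)
  ok <- defined & is.finite(theta)
  list(perLocus = data.frame(locus = rownames(d), a = a, b = b, c = cc,
                             theta = theta, defined = defined,
                             stringsAsFactors = FALSE),
       overall = overall, meanTheta = mean(theta[ok]),
       sdTheta = sd(theta[ok]), groups = levels(g))
}

#' Per-group allele counts for the outlier scan
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param groups named labels per individual id.
#' @return list with matrices \code{alt} and \code{tot} (loci x groups):
#'   alternate-allele counts and total called allele counts.
#' @export
alleleCounts <- function(x, groups) {
  d <- dosage(x)
  groups <- groups[colnames(d)]
  keep <- !is.na(groups)
  d <- d[, keep, drop = FALSE]
  g <- factor(groups[keep])
  alt <- vapply(levels(g), function(l)
    rowSums(d[, g == l, drop = FALSE], na.rm = TRUE), numeric(nrow(d)))
  tot <- vapply(levels(g), function(l)
    2 * rowSums(!is.na(d[, g == l, drop = FALSE])), numeric(nrow(d)))
  list(alt = matrix(alt, nrow = nrow(d)), tot = matrix(tot, nrow = nrow(d)),
       loci = rownames(d))
}

#' Bayesian F-ST outlier scan
#'
#' Reimplementation of the standard Bayesian outlier model for biallelic
#' allele counts: group allele frequencies follow a beta distribution
#' around a locus-specific ancestral frequency with
#' \code{logit(F_ij) = alpha_i + beta_j}; a reversible-jump MCMC toggles the
#' locus-specific selection term alpha_i in and out of the model with prior
#' odds \code{priorOdds} for neutrality.  Posterior inclusion probabilities
#' come from the post-burn-in thinned chain; q-values follow the
#' posterior-odds FDR convention (cumulative mean of 1 - PIP down the
#' ranked locus list) with decisions at \code{q <= qThreshold}.  Pilot runs
#' adapt the random-walk proposal SDs toward 25-45% acceptance.
#'
#' Default chain settings: prior odds 10, thinning 10, 20 pilot runs of
#' 5000, burn-in 50000, 10000 output iterations.  \code{preset = "reduced"}
#' uses 5 pilots of 500, burn-in 5000 and 2000 output iterations for
#' desk-scale runs.
#'
#' @param counts list from [alleleCounts()] (or matrices \code{alt}/
#'   \code{tot} of the same shape).
#' @param priorOdds prior odds for the neutral model (default 10).
#' @param nPilot,pilotLen,burnin,nOut,thin chain settings.
#' @param qThreshold decision threshold (default 0.05).
#' @param seed integer RNG seed.
#' @param preset "full" (defaults above) or "reduced".
#' @return an \linkS4class{OutlierScan}.
#' @export
bayescanScan <- function(counts, priorOdds = 10, nPilot = 20, pilotLen = 5000,
                         burnin = 50000, nOut = 10000, thin = 10,
                         qThreshold = 0.05, seed = 1L,
                         preset = c("full", "reduced")) {
  preset <- match.arg(preset)
  if (preset == "reduced") {
    nPilot <- 5; pilotLen <- 500; burnin <- 5000; nOut <- 2000
  }
  alt <- counts$alt; tot <- counts$tot
  if (nrow(alt) < 2)
    stop("scan refused: need >= 2 loci to estimate group effects")
  if (ncol(alt) < 2) stop("need >= 2 groups")
  set.seed(seed)
  res <- .bayescanMcmc(alt, tot, priorOdds, nPilot, pilotLen, burnin,
                       as.integer(nOut), as.integer(thin))
  pip <- res$pip
  o <- order(pip, decreasing = TRUE)
  q <- numeric(length(pip))
  q[o] <- cummean(1 - pip[o])
  ## enforce monotone non-decreasing q along the ranked list
  q[o] <- cummax(q[o])
  tab <- data.frame(locus = counts$loci %||% seq_along(pip),
                    pip = pip,
                    postOdds = pip / pmax(1 - pip, 1e-12),
                    q = q, alpha = res$alpha, fst = res$fst,
                    decision = q <= qThreshold,
                    stringsAsFactors = FALSE)
  diag <- list(accRatePi = res$accRatePi, kept = res$kept, beta = res$beta)
  if (res$accRatePi < 0.05)
    diag$warning <- "non-mixing chain: ancestral-frequency acceptance < 5%"
  settings <- list(priorOdds = priorOdds, nPilot = nPilot,
                   pilotLen = pilotLen, burnin = burnin, nOut = nOut,
                   thin = thin, qThreshold = qThreshold, preset = preset)
  new("OutlierScan", table = tab, settings = settings,
      seed = as.integer(seed), diagnostics = diag)
}

cummean <- function(x) cumsum(x) / seq_along(x)
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Union of outlier lists across scans
#'
#' @param scans list of \linkS4class{OutlierScan}.
#' @param qMax decision threshold (default 0.05).
#' @return data.frame: locus, nRuns (how many runs flagged it), runs
#'   (comma-separated run indices; per-run provenance).
#' @export
unionOutliers <- function(scans, qMax = 0.05) {
  hits <- lapply(seq_along(scans), function(i) {
    loci <- outlierLoci(scans[[i]], qMax)
    if (!length(loci)) return(NULL)
    data.frame(locus = loci, run = i, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits))
    return(data.frame(locus = character(), nRuns = integer(),
                      runs = character(), stringsAsFactors = FALSE))
  sp <- split(hits$run, hits$locus)
  data.frame(locus = names(sp),
             nRuns = lengths(sp),
             runs = vapply(sp, function(r) paste(sort(r), collapse = ","), ""),
             stringsAsFactors = FALSE, row.names = NULL)
}
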