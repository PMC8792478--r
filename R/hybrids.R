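hybridClasses <- c("P1", "P2", "F1", "F2", "BC1", "BC2")

## ancestry-copy mixing proportions: pi_k = P(genotype carries k alleles of
## parental-1 origin), Mendelian expectations per class
hybridMixing <- function() {
  m <- rbind(P1  = c(0,    0,   1),
             P2  = c(1,    0,   0),
             F1  = c(0,    1,   0),
             F2  = c(0.25, 0.5, 0.25),
             BC1 = c(0,    0.5, 0.5),
             BC2 = c(0.5,  0.5, 0))
  colnames(m) <- c("pi0", "pi1", "pi2")
  m
}

#' Build a hybrid-classification model from parental reference panels
#'
#' Estimates per-locus parental allele frequencies from designated reference
#' individuals of each species (in practice those with >99% admixture
#' membership) with additive smoothing
#' \code{(alt count + s) / (2 n_called + 2 s)}, and attaches the Mendelian
#' ancestry-copy mixing proportions of the six classes P1, P2, F1, F2, BC1,
#' BC2.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param panel1,panel2 character vectors of reference individual ids for
#'   parental species 1 and 2.
#' @param smoothing additive smoothing constant (default 0.5, Jeffreys-style;
#'   keeps frequencies strictly inside (0,1) at fixed differences).
#' @return a \linkS4class{HybridModel}.
#' @export
buildHybridModel <- function(x, panel1, panel2, smoothing = 0.5) {
  if (!length(panel1) || !length(panel2)) stop("a parental panel is empty")
  d <- dosage(x)
  freq <- function(ids) {
    sub <- d[, ids, drop = FALSE]
    alt <- rowSums(sub, na.rm = TRUE)
    nCalled <- rowSums(!is.na(sub))
    (alt + smoothing) / (2 * nCalled + 2 * smoothing)
  }
  new("HybridModel", p1 = freq(panel1), p2 = freq(panel2),
      mixing = hybridMixing(), smoothing = smoothing)
}

## genotype probability given k alleles of parental-1 origin:
## k=2 -> HW(p1); k=0 -> HW(p2); k=1 -> one allele from each parent pool
genoProbGivenCopies <- function(g, p1, p2) {
  hw <- function(p) switch(as.character(g),
                           "0" = (1 - p)^2, "1" = 2 * p * (1 - p), "2" = p^2)
  mixed <- switch(as.character(g),
                  "0" = (1 - p1) * (1 - p2),
                  "1" = p1 * (1 - p2) + p2 * (1 - p1),
                  "2" = p1 * p2)
  cbind(pi0 = hw(p2), pi1 = mixed, pi2 = hw(p1))
}

#' Posterior classification into parental and hybrid categories
#'
#' For each individual, the log-likelihood of each of the six classes is
#' summed over non-missing loci, with the per-locus genotype probability
#' \deqn{P(g | c) = \pi_2 HW(g; p_1) + \pi_0 HW(g; p_2) + \pi_1 M(g; p_1, p_2)}
#' where \eqn{M} is the genotype distribution of one allele from each
#' parental pool.  The posterior is proportional to \code{prior} times the
#' likelihood.  Individuals with zero non-missing loci get an NA posterior
#' row and label \code{"undefined"}.
#'
#' @param model a \linkS4class{HybridModel}.
#' @param x a \linkS4class{GenotypeMatrix} of the individuals to classify
#'   (must carry the same loci as the model).
#' @param prior class prior (default uniform over the six classes).
#' @return a \linkS4class{HybridPosterior}.
#' @export
classifyHybrids <- function(model, x, prior = rep(1 / 6, 6)) {
  d <- dosage(x)
  stopifnot(nrow(d) == length(model@p1), length(prior) == 6)
  prior <- prior / sum(prior)
  p1 <- model@p1; p2 <- model@p2
  mix <- model@mixing
  ## per-locus class likelihood components for g = 0, 1, 2 (6 x L each)
  likByG <- lapply(0:2, function(g) {
    comp <- genoProbGivenCopies(g, p1, p2)     # L x 3 (pi0, pi1, pi2)
    lg <- mix %*% t(comp)                      # 6 classes x L
    log(pmax(lg, 1e-300))
  })
  nI <- ncol(d)
  post <- matrix(NA_real_, nI, 6, dimnames = list(colnames(d), hybridClasses))
  nUsed <- integer(nI)
  for (i in seq_len(nI)) {
    g <- d[, i]
    ok <- !is.na(g)
    nUsed[i] <- sum(ok)
    if (!nUsed[i]) next
    lp <- log(prior)
    for (gv in 0:2) {
      sel <- ok & g == gv
      if (any(sel)) lp <- lp + rowSums(likByG[[gv + 1]][, sel, drop = FALSE])
    }
    lp <- lp - max(lp)
    post[i, ] <- exp(lp) / sum(exp(lp))
  }
  lab <- ifelse(nUsed == 0, "undefined", hybridClasses[max.col(replace(post, is.na(post), -1))])
  if (any(nUsed == 0)) warning(sum(nUsed == 0), " individual(s) with all loci missing")
  new("HybridPosterior", posterior = post, label = lab, nLociUsed = nUsed)
}

#' Subset SNPs for classification
#'
#' \code{mode = "first_n"} takes the first n loci in the dataset order;
#' \code{mode = "random_n"} samples n loci without replacement.  Requesting
#' more loci than available returns all loci with a warning.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param mode "first_n" or "random_n".
#' @param n number of loci (default 400).
#' @param seed integer, used for "random_n".
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
subsetSnps <- function(x, mode = c("first_n", "random_n"), n = 400, seed = 1L) {
  mode <- match.arg(mode)
  if (n >= nLoci(x)) {
    if (n > nLoci(x)) warning("n exceeds available loci; returning all")
    return(x)
  }
  idx <- if (mode == "first_n") seq_len(n) else {
    set.seed(seed)
    sort(sample.int(nLoci(x), n))
  }
  x[idx, ]
}

#' Hybridization rate from class labels
#'
#' \code{rate = n_F1 / (n_F1 + n_P1 + n_P2)}: the proportion of F1 hybrids
#' relative to individuals in the two parental classes.  F2 and backcross
#' individuals are reported separately and excluded from the denominator.
#'
#' @param labels character vector of class labels (P1/P2/F1/F2/BC1/BC2).
#' @param keep optional logical vector (same length) restricting to a
#'   region, e.g. the zone of sympatry.
#' @return list: \code{rate}, \code{percent} (1 d.p.), \code{nF1},
#'   \code{denominator}, \code{nOther} (F2 + backcrosses), and a formatted
#'   \code{text} "x% (a of b)".
#' @examples
#' r <- hybridizationRate(c(rep("P1", 100), rep("P2", 69), rep("F1", 5)))
#' r$text  # "2.9% (5 of 174)"
#' @export
hybridizationRate <- function(labels, keep = NULL) {
  if (!is.null(keep)) labels <- labels[keep]
  nF1 <- sum(labels == "F1")
  den <- nF1 + sum(labels %in% c("P1", "P2"))
  rate <- if (den > 0) nF1 / den else NA_real_
  list(rate = rate,
       percent = round(100 * rate, 1),
       nF1 = nF1, denominator = den,
       nOther = sum(labels %in% c("F2", "BC1", "BC2")),
       text = sprintf("%.1f%% (%d of %d)", 100 * rate, nF1, den))
}
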