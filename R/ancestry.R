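#' Principal component analysis of genotype dosages
#'
#' Missing dosages are replaced by the locus mean, the matrix is
#' mean-centered per locus, and scores are obtained by singular value
#' decomposition of the individuals-by-loci matrix.  Loci that are entirely
#' missing are excluded with a warning.  Scores are deterministic up to sign.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param nComponents number of components to return.
#' @return list: \code{scores} (individuals x components),
#'   \code{explained} (variance fractions), \code{sdev}.
#' @export
genoPca <- function(x, nComponents = 2) {
  d <- dosage(x)
  if (nrow(d) < 2 || ncol(d) < 2) stop("need >= 2 individuals and >= 2 loci")
  allMiss <- rowSums(!is.na(d)) == 0
  if (any(allMiss)) {
    warning(sum(allMiss), " all-missing locus/loci excluded")
    d <- d[!allMiss, , drop = FALSE]
  }
  mu <- rowMeans(d, na.rm = TRUE)
  d[is.na(d)] <- mu[row(d)[is.na(d)]]
  cen <- t(d - mu)                      # individuals x loci
  sv <- svd(cen, nu = min(nComponents, ncol(cen), nrow(cen)), nv = 0)
  k <- min(nComponents, length(sv$d))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- colnames(dosage(x))
  colnames(scores) <- paste0("PC", seq_len(k))
  ev <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, explained = ev[seq_len(k)], sdev = sv$d / sqrt(max(1, nrow(cen) - 1)))
}

#' Maximum-likelihood admixture model fit by EM
#'
#' Fits the standard admixture model for unlinked biallelic dosages: each of
#' an individual's two allele copies at locus l derives from cluster k with
#' probability Q[i,k] and is then the alternate allele with probability
#' P[k,l], so the dosage is Binomial(2, sum_k Q[i,k] P[k,l]).  Parameters
#' are maximized by expectation-maximization; the log-likelihood is
#' non-decreasing across iterations and iteration stops when its change
#' drops below \code{tol} or at \code{maxIter}.  Missing genotypes are
#' skipped per locus.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param k number of clusters (>= 1).
#' @param seed integer; determines the random initialisation.
#' @param maxIter maximum EM iterations.
#' @param tol absolute log-likelihood convergence tolerance.
#' @return an \linkS4class{AdmixtureFit}.
#' @export
fitAdmixture <- function(x, k, seed = 1L, maxIter = 500, tol = 1e-6) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  d <- dosage(x)
  nI <- ncol(d); nL <- nrow(d)
  if (k > nI) stop("k must not exceed the number of individuals")
  g <- t(d)                              # individuals x loci
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0                 # alt-copy counts, 0 where missing
  h0 <- (2 - g); h0[!obs] <- 0           # ref-copy counts
  set.seed(seed)
  Q <- matrix(rgamma(nI * k, 1), nI, k); Q <- Q / rowSums(Q)
  P <- matrix(runif(k * nL, 0.05, 0.95), k, nL)
  eps <- 1e-9
  ll <- function() {
    f <- Q %*% P
    f <- pmin(pmax(f, eps), 1 - eps)
    sum(g0 * log(f) + h0 * log1p(-f))
  }
  trace <- numeric(0)
  prev <- -Inf
  it <- 0L; converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    f <- Q %*% P
    f <- pmin(pmax(f, eps), 1 - eps)
    ## E-step responsibilities, folded into the M-step sums:
    ## alt copies at (i,l) assign to cluster k w.p. Q[i,k]P[k,l]/f[i,l]
    A <- g0 / f                          # individuals x loci
    B <- h0 / (1 - f)
    ## per-cluster expected alt / ref copy counts
    EaQ <- (A %*% t(P)) * Q              # individuals x k : sum_l a contributions
    EbQ <- (B %*% t(1 - P)) * Q
    Qnew <- EaQ + EbQ
    Qnew <- Qnew / rowSums(Qnew)
    Ea <- t(Q) %*% A * P                 # k x loci expected alt copies
    Eb <- t(Q) %*% B * (1 - P)
    Pnew <- Ea / (Ea + Eb)
    Pnew[!is.finite(Pnew)] <- 0.5
    Q <- Qnew; P <- pmin(pmax(Pnew, eps), 1 - eps)
    cur <- ll()
    trace <- c(trace, cur)
    if (is.finite(prev) && abs(cur - prev) < tol) { converged <- TRUE; break }
    prev <- cur
  }
  rownames(Q) <- colnames(d)
  new("AdmixtureFit", k = k, Q = Q, P = P, loglik = trace[length(trace)],
      loglikTrace = trace, nIter = it, converged = converged,
      seed = as.integer(seed))
}

#' Fit replicate admixture runs over a range of k
#'
#' Runs \code{nReplicates} seeds for each k in \code{1..kMax} and aligns the
#' replicates of each k by greedy cluster matching on the correlation of
#' allele-frequency vectors before averaging Q.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param kMax largest k.
#' @param nReplicates replicate seeds per k (>= 3 for a defined sd in
#'   [selectK()]).
#' @param seed base seed; replicate r of k uses \code{seed + 1000*k + r}.
#' @param ... passed to [fitAdmixture()].
#' @return list of lists of \linkS4class{AdmixtureFit}, indexed by k.
#' @export
replicateAdmixture <- function(x, kMax = 3, nReplicates = 3, seed = 1L, ...) {
  fits <- lapply(seq_len(kMax), function(k)
    lapply(seq_len(nReplicates), function(r)
      fitAdmixture(x, k, seed = seed + 1000L * k + r, ...)))
  names(fits) <- paste0("k", seq_len(kMax))
  fits
}

## align fit b's clusters to fit a's by greedy matching on P correlation
alignClusters <- function(a, b) {
  k <- a@k
  if (k == 1) return(b)
  cc <- suppressWarnings(stats::cor(t(a@P), t(b@P)))
  cc[!is.finite(cc)] <- 0
  perm <- integer(k)
  used <- logical(k)
  for (i in order(-apply(cc, 1, max))) {
    j <- order(-cc[i, ])
    j <- j[!used[j]][1]
    perm[i] <- j; used[j] <- TRUE
  }
  b@Q <- b@Q[, perm, drop = FALSE]
  b@P <- b@P[perm, , drop = FALSE]
  b
}

#' Average aligned replicate fits of one k
#'
#' @param fits list of \linkS4class{AdmixtureFit} with equal k.
#' @return an \linkS4class{AdmixtureFit} with averaged Q and P and the mean
#'   log-likelihood.
#' @export
averageAdmixture <- function(fits) {
  ref <- fits[[which.max(vapply(fits, function(f) f@loglik, 0))]]
  al <- lapply(fits, alignClusters, a = ref)
  Q <- Reduce(`+`, lapply(al, function(f) f@Q)) / length(al)
  Q <- Q / rowSums(Q)
  P <- Reduce(`+`, lapply(al, function(f) f@P)) / length(al)
  new("AdmixtureFit", k = ref@k, Q = Q, P = pmin(pmax(P, 0), 1),
      loglik = mean(vapply(fits, function(f) f@loglik, 0)),
      loglikTrace = ref@loglikTrace, nIter = ref@nIter,
      converged = all(vapply(fits, function(f) f@converged, TRUE)),
      seed = ref@seed)
}

#' Select the number of clusters from replicate log-likelihoods
#'
#' Reports both criteria: mean LnP(k) per k, and the Evanno-style
#' second-order statistic
#' \deqn{\Delta k = mean(|L(k+1) - 2 L(k) + L(k-1)|) / sd(L(k))}
#' defined for interior k only.  The chosen k is the \eqn{\Delta k} argmax;
#' when no \eqn{\Delta k} is defined (kMax <= 2) or the likelihood surface
#' is flat, selection falls back to the LnP(k) plateau and is flagged
#' ambiguous.
#'
#' @param fits replicate fits as returned by [replicateAdmixture()], or a
#'   numeric matrix of log-likelihoods (replicates x k).
#' @return list of class \code{"KSelection"}: \code{logliks} matrix,
#'   \code{meanLnPk}, \code{deltaK} (NA at the boundaries and where sd = 0),
#'   \code{chosenK}, \code{ambiguous}.
#' @export
selectK <- function(fits) {
  L <- if (is.matrix(fits)) fits else
    vapply(fits, function(fk) vapply(fk, function(f) f@loglik, 0),
           numeric(length(fits[[1]])))
  kMax <- ncol(L)
  if (min(table(col(L))) < 3 && nrow(L) < 3)
    warning("fewer than 3 replicates per k; sd-based criteria unreliable")
  mLnP <- colMeans(L)
  sdL <- apply(L, 2, sd)
  deltaK <- rep(NA_real_, kMax)
  for (k in seq_len(kMax)) {
    if (k == 1 || k == kMax) next
    if (!is.finite(sdL[k]) || sdL[k] == 0) next     # flagged undefined
    deltaK[k] <- mean(abs(L[, k + 1] - 2 * L[, k] + L[, k - 1])) / sdL[k]
  }
  ambiguous <- all(!is.finite(deltaK)) ||
    (max(deltaK, na.rm = TRUE) < 1 && all(abs(diff(mLnP)) < 1e-6))
  chosen <- if (any(is.finite(deltaK))) which.max(deltaK)
            else which.max(mLnP)                    # LnP(k) fallback
  out <- list(logliks = L, meanLnPk = mLnP, deltaK = deltaK,
              chosenK = as.integer(chosen), ambiguous = ambiguous)
  class(out) <- "KSelection"
  out
}

#' @export
print.KSelection <- function(x, ...) {
  cat("KSelection: chosen k =", x$chosenK,
      if (x$ambiguous) "(ambiguous)" else "", "\n")
  print(data.frame(k = seq_along(x$meanLnPk), meanLnPk = x$meanLnPk,
                   deltaK = x$deltaK))
  invisible(x)
}

#' Assign species labels from admixture membership
#'
#' Individuals with strictly more than \code{threshold} membership to one of
#' two clusters receive that cluster's species label; all others are
#' \code{"ambiguous"} (candidate hybrids, forwarded to the hybrid
#' classifier).  Cluster-to-species naming uses anchor individuals: each
#' cluster is named after the species whose anchors have the higher mean
#' membership in it.  An exact threshold membership (e.g. 0.90) is
#' ambiguous: the rule is strict.
#'
#' @param fit an \linkS4class{AdmixtureFit} with k = 2.
#' @param threshold membership threshold (default 0.90).
#' @param anchors optional named list of two character vectors of sample
#'   ids, names = species labels.  Without anchors, labels are
#'   \code{"cluster1"}/\code{"cluster2"}.
#' @return named character vector of labels per individual.
#' @export
assignSpecies <- function(fit, threshold = 0.90, anchors = NULL) {
  stopifnot(fit@k == 2)
  Q <- fit@Q
  names1 <- c("cluster1", "cluster2")
  if (!is.null(anchors)) {
    stopifnot(length(anchors) == 2, !is.null(names(anchors)))
    m <- vapply(anchors, function(ids) colMeans(Q[ids, , drop = FALSE]),
                numeric(2))                         # 2 clusters x 2 species
    sp1Cluster <- which.max(m[, 1])
    names1[sp1Cluster] <- names(anchors)[1]
    names1[3 - sp1Cluster] <- names(anchors)[2]
  }
  lab <- ifelse(Q[, 1] > threshold, names1[1],
                ifelse(Q[, 2] > threshold, names1[2], "ambiguous"))
  setNames(lab, rownames(Q))
}

#' Resolve substructure within one species
#'
#' Subsets the genotype matrix to the individuals carrying a given species
#' label (excluding F1 hybrids if hybrid labels are supplied), refilters the
#' subset with the same SNP filters, and runs replicate admixture fits with
#' K selection.  Subspecies labels use the majority (> 0.5) coefficient.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param labels named character vector of species labels (from
#'   [assignSpecies()]).
#' @param species the species label to analyse.
#' @param hybridLabels optional named character vector; individuals labelled
#'   "F1" are excluded.
#' @param kMax,nReplicates,seed passed to [replicateAdmixture()].
#' @param callRateMin,mafMin,thinBp passed to [filterVariants()].
#' @return list: \code{fit} (averaged k=2 \linkS4class{AdmixtureFit}),
#'   \code{kSelection}, \code{subLabels} (majority-coefficient labels
#'   "sub1"/"sub2"), \code{genotypes} (the refiltered subset).
#' @export
substructure <- function(x, labels, species, hybridLabels = NULL,
                         kMax = 3, nReplicates = 3, seed = 1L,
                         callRateMin = 0.95, mafMin = 0.10, thinBp = 10000) {
  ids <- names(labels)[labels == species]
  if (!is.null(hybridLabels))
    ids <- setdiff(ids, names(hybridLabels)[hybridLabels == "F1"])
  if (length(ids) < 2) stop("need >= 2 individuals of species ", species)
  sub <- x[, ids]
  sub <- filterVariants(sub, callRateMin, mafMin, thinBp)
  if (nLoci(sub) < 2) stop("too few loci after refiltering")
  fits <- replicateAdmixture(sub, kMax = kMax, nReplicates = nReplicates,
                             seed = seed)
  ks <- selectK(fits)
  f2 <- averageAdmixture(fits[[2]])
  subLab <- ifelse(f2@Q[, 1] > 0.5, "sub1", "sub2")
  list(fit = f2, kSelection = ks,
       subLabels = setNames(subLab, rownames(f2@Q)), genotypes = sub)
}
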