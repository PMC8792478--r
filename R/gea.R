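#' Latent-factor genotype-environment association scan
#'
#' Confounder-adjusted association testing in the spirit of latent factor
#' mixed models: latent factors are the top-K left singular vectors of the
#' centered (locus-mean-imputed) genotype matrix; each locus's dosage is
#' regressed on each standardized environmental variable plus the factors;
#' the environment coefficient's z-score is rescaled by the
#' genomic-inflation factor (median z^2 / 0.456) before p-values, and
#' Benjamini-Hochberg q-values are computed per variable.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param env data.frame keyed by \code{location} with environmental
#'   variables (all non-location columns used unless \code{variables} set).
#' @param samples data.frame with \code{id}, \code{location} joining each
#'   genotyped individual to a location; every individual in \code{x} must
#'   be present.
#' @param K number of latent factors (0 = none); must be < individuals.
#' @param variables optional character vector of variable names.
#' @return a \linkS4class{GEAScan}.  Constant variables are excluded with a
#'   warning; variables collinear with the factors are reported in the
#'   table with NA statistics.
#' @export
geaScan <- function(x, env, samples, K = 2, variables = NULL) {
  d <- dosage(x)
  ids <- colnames(d)
  loc <- setNames(samples$location, samples$id)[ids]
  if (any(is.na(loc))) stop("individual(s) without location: ",
                            paste(head(ids[is.na(loc)], 5), collapse = ", "))
  ev <- env[match(loc, env$location), setdiff(names(env), "location"),
            drop = FALSE]
  if (any(is.na(ev))) stop("location(s) without environment values")
  if (!is.null(variables)) ev <- ev[, variables, drop = FALSE]
  n <- length(ids)
  if (K >= n) stop("K must be < number of individuals")
  ## centered, imputed genotypes: individuals x loci
  mu <- rowMeans(d, na.rm = TRUE)
  d[is.na(d)] <- mu[row(d)[is.na(d)]]
  G <- t(d - mu)
  U <- if (K > 0) svd(G, nu = K, nv = 0)$u else NULL
  keepVar <- vapply(ev, function(v) sd(v) > 0, TRUE)
  if (any(!keepVar))
    warning("constant variable(s) excluded: ",
            paste(names(ev)[!keepVar], collapse = ", "))
  vars <- names(ev)[keepVar]
  out <- list(); lambda <- setNames(numeric(0), character(0))
  for (v in vars) {
    e <- scale(ev[[v]])[, 1]
    D <- cbind(1, e, U)
    if (qr(D)$rank < ncol(D)) {      # environment collinear with factors
      out[[v]] <- data.frame(locus = rownames(d), variable = v,
                             beta = NA_real_, z = NA_real_, p = NA_real_,
                             q = NA_real_, stringsAsFactors = FALSE)
      lambda[v] <- NA_real_
      next
    }
    fit <- lm.fit(D, G)
    beta <- fit$coefficients[2, ]
    df <- n - ncol(D)
    sigma2 <- colSums(fit$residuals^2) / df
    xtxInv22 <- chol2inv(chol(crossprod(D)))[2, 2]
    z <- beta / sqrt(sigma2 * xtxInv22)
    lam <- median(z^2, na.rm = TRUE) / qchisq(0.5, 1)
    lam <- max(lam, 1e-8)
    pcal <- pchisq(z^2 / lam, 1, lower.tail = FALSE)
    out[[v]] <- data.frame(locus = rownames(d), variable = v, beta = beta,
                           z = z, p = pcal, q = p.adjust(pcal, "BH"),
                           stringsAsFactors = FALSE, row.names = NULL)
    lambda[v] <- lam
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  new("GEAScan", table = tab, K = as.integer(K), lambda = lambda,
      variables = vars)
}

#' Strongest environmental variable per significant locus
#'
#' For loci significant for more than one variable (common under spatial
#' correlation of climate variables), assigns the variable with the largest
#' median |z| across replicate scans.  Exact ties break lexicographically
#' and are flagged.
#'
#' @param scans list of \linkS4class{GEAScan} replicates (>= 1).
#' @param qMax significance threshold (default 0.05).
#' @return data.frame: locus, variable, medianAbsZ, nSignif, tie.
#' @export
strongestVariable <- function(scans, qMax = 0.05) {
  if (inherits(scans, "GEAScan")) scans <- list(scans)
  all <- do.call(rbind, lapply(seq_along(scans), function(i)
    cbind(geaTable(scans[[i]]), rep = i)))
  sig <- unique(all[!is.na(all$q) & all$q <= qMax, c("locus", "variable")])
  if (!nrow(sig))
    return(data.frame(locus = character(), variable = character(),
                      medianAbsZ = numeric(), nSignif = integer(),
                      tie = logical(), stringsAsFactors = FALSE))
  medz <- stats::aggregate(z ~ locus + variable, data = all,
                           FUN = function(z) median(abs(z)))
  res <- lapply(split(sig, sig$locus), function(s) {
    m <- medz[medz$locus == s$locus[1] & medz$variable %in% s$variable, ]
    m <- m[order(m$variable), ]
    best <- which.max(m$z)
    data.frame(locus = s$locus[1], variable = m$variable[best],
               medianAbsZ = m$z[best], nSignif = nrow(s),
               tie = sum(m$z == max(m$z)) > 1, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

#' Group-wise genotype-environment scans
#'
#' Runs [geaScan()] for each named group of individuals (e.g. all
#' individuals, each species independently), refiltering the genotype
#' subset first and choosing K per group from replicate admixture fits when
#' not supplied.  Groups whose individuals span fewer than 3 locations with
#' distinct environments are refused (rank-deficient design).
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param groups named list of character vectors of individual ids.
#' @param env,samples as in [geaScan()].
#' @param K named integer vector of factor counts per group, or NULL to
#'   select per group via [selectK()] on replicate admixture fits.
#' @param seed integer.
#' @param callRateMin,mafMin,thinBp filter settings.
#' @return named list of \linkS4class{GEAScan} (entries NULL with a warning
#'   for refused groups).
#' @export
groupedScans <- function(x, groups, env, samples, K = NULL, seed = 1L,
                         callRateMin = 0.95, mafMin = 0.10, thinBp = 10000) {
  out <- vector("list", length(groups))
  names(out) <- names(groups)
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], sampleIds(x))
    locs <- unique(samples$location[samples$id %in% ids])
    evSub <- unique(env[env$location %in% locs, setdiff(names(env), "location")])
    if (length(locs) < 3 || nrow(evSub) < 3) {
      warning("group '", g, "' refused: fewer than 3 distinct-environment locations")
      next
    }
    sub <- filterVariants(x[, ids], callRateMin, mafMin, thinBp)
    kg <- if (!is.null(K)) K[[g]] else {
      fits <- replicateAdmixture(sub, kMax = 3, nReplicates = 3, seed = seed)
      selectK(fits)$chosenK
    }
    out[[g]] <- geaScan(sub, env, samples, K = kg)
  }
  out
}
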