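# shared fixture builders; everything is generated in code

# GenotypeMatrix from a loci x individuals dosage matrix, loci on one
# scaffold at the given positions (default 10 kb apart so thinning keeps all)
makeGm <- function(d, pos = NULL, scaffold = "s1") {
  d <- as.matrix(d)
  if (is.null(colnames(d))) colnames(d) <- paste0("i", seq_len(ncol(d)))
  if (is.null(pos)) pos <- seq_len(nrow(d)) * 10000
  GenotypeMatrix(d, data.frame(scaffold = scaffold, pos = pos))
}

# two-population HW genotypes with known per-population frequencies,
# loci in a fixed order (single scaffold), planted indices preserved
makeTwoPopGm <- function(p1, p2, n1, n2, seed = 1) {
  set.seed(seed)
  L <- length(p1)
  g1 <- matrix(rbinom(L * n1, 2, rep(p1, n1)), L)
  g2 <- matrix(rbinom(L * n2, 2, rep(p2, n2)), L)
  d <- cbind(g1, g2)
  colnames(d) <- c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
  list(gm = makeGm(d),
       groups = setNames(rep(c("g1", "g2"), c(n1, n2)), colnames(d)))
}

# geometric oracle for the triangle diurnal curve: the diurnal temperature
# is piecewise linear (tmin -> tmax over half a day, back over the other
# half); the area above thr is computed by clipping each linear segment
# against the threshold, an independent (and exact) formulation
segmentAreaAbove <- function(y0, y1, dx, thr) {
  if (y0 <= thr && y1 <= thr) return(0)
  if (y0 >= thr && y1 >= thr) return(dx * ((y0 + y1) / 2 - thr))
  hi <- max(y0, y1)
  dx * (hi - thr)^2 / (2 * abs(y1 - y0))
}
triangleAreaOracle <- function(tmin, tmax, thr) {
  if (tmax == tmin) return(max(tmin - thr, 0))
  segmentAreaAbove(tmin, tmax, 0.5, thr) + segmentAreaAbove(tmax, tmin, 0.5, thr)
}

# exhaustive pair-counting Mann-Whitney U oracle (0.5 per tie)
uOracle <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# direct scalar evaluation of the Weir-Cockerham (1984) two-allele variance
# components from per-group genotype count tables (list of c(n0, n1, n2))
wcOracle <- function(tables) {
  r <- length(tables)
  n <- vapply(tables, sum, 0)
  p <- vapply(tables, function(t) (t[2] + 2 * t[3]) / (2 * sum(t)), 0)
  h <- vapply(tables, function(t) t[2] / sum(t), 0)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# brute-force Benjamini-Hochberg discovery set
bhOracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  if (!length(k)) return(integer(0))
  sort(o[seq_len(max(k))])
}

# study-shaped association-scan dataset: n individuals over nLoc locations
# on a climate gradient; optionally with planted gradient-linked loci or a
# two-deme structure confounded with the gradient
geaFixture <- function(n = 60, L = 100, nLoc = 6, seed = 1,
                       planted = integer(0), confounded = FALSE) {
  set.seed(seed)
  loc <- paste0("L", seq_len(nLoc))
  grad <- seq(-1, 1, length.out = nLoc)
  indLoc <- rep(loc, length.out = n)
  indGrad <- grad[match(indLoc, loc)]
  p <- runif(L, 0.2, 0.8)
  d <- matrix(rbinom(L * n, 2, rep(p, n)), L)
  for (j in planted) {
    pr <- pmin(pmax(0.5 + 0.45 * indGrad, 0.02), 0.98)
    d[j, ] <- rbinom(n, 2, pr)
  }
  if (confounded) {
    pop <- ifelse(indGrad > 0, 1, 0)
    for (j in planted) d[j, ] <- rbinom(n, 2, ifelse(pop == 1, 0.9, 0.1))
    bg <- sample(setdiff(seq_len(L), planted), 40)
    for (j in bg) {
      pj <- runif(2, 0.1, 0.9)
      d[j, ] <- rbinom(n, 2, pj[pop + 1])
    }
  }
  colnames(d) <- sprintf("i%03d", seq_len(n))
  env <- data.frame(location = loc, var1 = grad, var2 = rnorm(nLoc))
  samples <- data.frame(id = colnames(d), location = indLoc)
  list(gm = makeGm(d), env = env, samples = samples)
}

# small staggered-phenology scenario used by overlap contrast checks
staggeredConfig <- function(seed, nLoci = 50) {
  simConfig(nLoci = nLoci, seed = seed)
}
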