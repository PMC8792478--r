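test_that("PCA separates diverged populations and matches a dense eigensolver", {
  tp <- makeTwoPopGm(rep(0.95, 80), rep(0.05, 80), 12, 12, seed = 1)
  pc <- genoPca(tp$gm, 2)
  s1 <- pc$scores[tp$groups == "g1", 1]
  s2 <- pc$scores[tp$groups == "g2", 1]
  expect_true(max(min(s1), min(s2)) > min(max(s1), max(s2)) ||
                all(s1 > max(s2)) || all(s1 < min(s2)))

  # duplicated individual gets identical scores
  d <- dosage(tp$gm)
  d <- cbind(d, dup = d[, 1])
  pc2 <- genoPca(makeGm(d), 2)
  expect_equal(unname(pc2$scores["dup", ]), unname(pc2$scores[1, ]))

  # 5x5 fixture: squared singular values / (n-1) equal covariance eigenvalues
  set.seed(9)
  d5 <- matrix(rbinom(25, 2, 0.5), 5, dimnames = list(NULL, paste0("i", 1:5)))
  gm5 <- makeGm(d5)
  pc5 <- genoPca(gm5, 5)
  cen <- t(d5 - rowMeans(d5))
  ev <- eigen(stats::cov(cen), symmetric = TRUE)$values
  expect_equal(pc5$sdev[1:4]^2, ev[1:4], tolerance = 1e-8)
})

test_that("EM admixture recovers trivial configurations and is monotone", {
  # two individuals fixed for opposite alleles
  d <- cbind(a = rep(2L, 30), b = rep(0L, 30))
  fit <- fitAdmixture(makeGm(d), 2, seed = 1)
  Q <- membership(fit)
  expect_true(all(apply(Q, 1, max) > 0.999))
  expect_lt(sum(Q[, 1] > 0.5), 2)   # the two sit in different clusters

  # fully heterozygous individual at fixed differences sits at 50/50
  d2 <- cbind(a = rep(2L, 60), b = rep(0L, 60), h = rep(1L, 60))
  fit2 <- fitAdmixture(makeGm(d2), 2, seed = 2)
  expect_equal(unname(membership(fit2)["h", ]), c(0.5, 0.5), tolerance = 0.02)

  # log-likelihood never decreases
  tp <- makeTwoPopGm(runif(100, 0.6, 0.95), runif(100, 0.05, 0.4), 8, 8, seed = 3)
  fit3 <- fitAdmixture(tp$gm, 2, seed = 3)
  expect_true(all(diff(fit3@loglikTrace) > -1e-6))

  expect_error(fitAdmixture(tp$gm, 20), "exceed")
})

test_that("EM attains at least the grid-search optimum for fixed true P", {
  set.seed(5)
  p1 <- runif(20, 0.8, 0.95); p2 <- runif(20, 0.05, 0.2)
  tp <- makeTwoPopGm(p1, p2, 3, 3, seed = 5)
  fit <- fitAdmixture(tp$gm, 2, seed = 5, maxIter = 2000, tol = 1e-10)
  # oracle: coarse grid over each individual's q with P fixed at the truth
  d <- dosage(tp$gm)
  qGrid <- seq(0, 1, by = 0.01)
  gridLL <- sum(vapply(seq_len(ncol(d)), function(i) {
    g <- d[, i]
    best <- -Inf
    for (q in qGrid) {
      f <- pmin(pmax(q * p1 + (1 - q) * p2, 1e-9), 1 - 1e-9)
      ll <- sum(g * log(f) + (2 - g) * log(1 - f))
      if (ll > best) best <- ll
    }
    best
  }, 0))
  expect_gte(fit@loglik, gridLL - 1e-4)
})

test_that("cluster-number selection reproduces a hand-computed delta-k", {
  # fabricated replicate log-likelihood table, 3 replicates x k = 1..4,
  # sharp elbow at k = 2
  L <- rbind(c(-1000, -800, -790, -785),
             c(-1002, -801, -789, -784),
             c(-1001, -799, -791, -786))
  ks <- selectK(L)
  # hand computation for k = 2: mean|L3 - 2 L2 + L1| / sd(L2)
  d2 <- mean(abs(L[, 3] - 2 * L[, 2] + L[, 1])) / sd(L[, 2])
  d3 <- mean(abs(L[, 4] - 2 * L[, 3] + L[, 2])) / sd(L[, 3])
  expect_equal(ks$deltaK[2], d2)
  expect_equal(ks$deltaK[3], d3)
  expect_true(is.na(ks$deltaK[1]) && is.na(ks$deltaK[4]))
  expect_equal(ks$chosenK, 2L)

  # flat likelihoods: ambiguous
  Lf <- matrix(rep(c(-500, -500, -500), 4), 3)
  ksf <- selectK(Lf)
  expect_true(ksf$ambiguous)

  # kMax = 2: no interior k, fall back to LnP(k)
  L2 <- rbind(c(-900, -700), c(-901, -702), c(-899, -701))
  ks2 <- selectK(L2)
  expect_true(all(is.na(ks2$deltaK)))
  expect_equal(ks2$chosenK, 2L)
})

test_that("species assignment applies a strict membership threshold", {
  Q <- rbind(a = c(0.95, 0.05), b = c(0.55, 0.45), c = c(0.90, 0.10),
             d = c(0.08, 0.92))
  fit <- new("AdmixtureFit", k = 2L, Q = Q,
             P = matrix(c(0.9, 0.1), 2, 5), loglik = -1, loglikTrace = -1,
             nIter = 1L, converged = TRUE, seed = 1L)
  lab <- assignSpecies(fit, 0.90)
  expect_equal(unname(lab), c("cluster1", "ambiguous", "ambiguous", "cluster2"))

  # anchor mapping names clusters and is invariant to label swap
  lab1 <- assignSpecies(fit, 0.90, anchors = list(fum = "a", occ = "d"))
  fitSw <- fit
  fitSw@Q <- Q[, 2:1]
  fitSw@P <- fit@P[2:1, , drop = FALSE]
  lab2 <- assignSpecies(fitSw, 0.90, anchors = list(fum = "a", occ = "d"))
  expect_equal(lab1, lab2)
  expect_equal(unname(lab1["a"]), "fum")
  expect_equal(unname(lab1["d"]), "occ")
})

test_that("within-species substructure is recovered at shallow divergence", {
  # one species containing two sub-demes at F = 0.01
  set.seed(31)
  f <- simulateAlleleFreqs(2000, 0.01, c(0.2, 0.5), seed = 31)
  tp <- makeTwoPopGm(f$p1, f$p2, 25, 25, seed = 31)
  labels <- setNames(rep("occ", 50), sampleIds(tp$gm))
  res <- substructure(tp$gm, labels, "occ", seed = 31,
                      callRateMin = 0.9, mafMin = 0.05, thinBp = 0)
  agree <- mean(res$subLabels == ifelse(tp$groups == "g1", "sub1", "sub2"))
  expect_gte(max(agree, 1 - agree), 0.9)

  expect_error(substructure(tp$gm, labels[1], "occ"), ">= 2")
})
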