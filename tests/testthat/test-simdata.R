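test_that("divergence model hits its boundary cases and rejects bad input", {
  f0 <- simulateAlleleFreqs(200, 0, seed = 1)
  expect_equal(f0$p1, f0$p2)
  expect_equal(f0$p1, f0$anc)

  f1 <- simulateAlleleFreqs(200, 1, seed = 1)
  expect_true(all(f1$p1 %in% c(0, 1)))
  expect_true(all(f1$p2 %in% c(0, 1)))

  expect_error(simulateAlleleFreqs(10, 1.2, seed = 1), "fstTarget")
  expect_error(simulateAlleleFreqs(10, 0.3, c(0, 0.6), seed = 1), "Range")
})

test_that("realized between-population F_ST tracks the divergence parameter", {
  # averaged over seeds at 2000 loci, the Weir-Cockerham estimate over
  # simulated genotypes should land within 0.05 of the target
  fst <- vapply(1:3, function(s) {
    f <- simulateAlleleFreqs(2000, 0.34, seed = s)
    g <- simulateGenotypes(f, list(nPop1 = 40, nPop2 = 40, nF1 = 0, nF2 = 0,
                                   nBc1 = 0, nBc2 = 0), 0, seed = s)
    grp <- setNames(g$truth$class, g$truth$id)
    wcFst(g$genotypes, grp)$overall
  }, 0)
  expect_lt(abs(mean(fst) - 0.34), 0.05)
})

test_that("cross genotypes follow Mendelian expectations", {
  # fixed difference: every F1 heterozygous
  f <- data.frame(anc = rep(0.5, 30), p1 = rep(1, 30), p2 = rep(0, 30))
  g <- simulateGenotypes(f, list(nPop1 = 2, nPop2 = 2, nF1 = 10, nF2 = 0,
                                 nBc1 = 0, nBc2 = 0), 0, seed = 2)
  f1 <- dosage(g$genotypes)[, g$truth$class == "F1"]
  expect_true(all(f1 == 1))

  # no missing calls at missingRate = 0
  expect_false(anyNA(dosage(g$genotypes)))

  # F2 at fixed-difference loci segregate ~1:2:1
  g2 <- simulateGenotypes(f, list(nPop1 = 0, nPop2 = 0, nF1 = 0, nF2 = 60,
                                  nBc1 = 0, nBc2 = 0), 0, seed = 3)
  counts <- table(factor(dosage(g2$genotypes), levels = 0:2))
  chi <- chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 0.001)
})

test_that("temperature generator keeps tmax >= tmin and honors the logger offset", {
  t0 <- simulateTemperature("a", 2018, tempOffsetC = 0, loggerOffsetC = 1.5,
                            seed = 5, noiseSd = 0, loggerNoiseSd = 0)
  st <- t0[t0$source == "station", ]
  lg <- t0[t0$source == "logger", ]
  expect_equal(median(lg$tmax - st$tmax), 1.5)
  expect_equal(median(lg$tmin - st$tmin), 1.5)

  t1 <- simulateTemperature("b", 2017, tempOffsetC = -1, loggerOffsetC = 0.7,
                            seed = 9)
  expect_true(all(t1$tmax >= t1$tmin))
  expect_equal(min(t1$date), as.Date("2017-01-01"))

  # zero offset, zero noise: logger identical to station
  t2 <- simulateTemperature("c", 2018, loggerOffsetC = 0, seed = 5,
                            noiseSd = 0, loggerNoiseSd = 0)
  expect_equal(t2$tmax[t2$source == "logger"], t2$tmax[t2$source == "station"])
})

test_that("emergence is degree-day driven, ordered, and parity-respecting", {
  cfg <- simConfig(nLoci = 20, nPop1 = 15, nPop2 = 15, nF1 = 0,
                   ddNoiseSd = 0, offYearFraction = 0, seed = 11)
  st <- simulateStudy(cfg)
  em <- st$truth[!is.na(st$truth$emergence), ]
  # no individual noise: same class/location/year emerge the same day
  key <- paste(em$class, em$location, em$year)
  spread <- tapply(em$emergence, key, function(d) diff(range(d)))
  expect_true(all(spread == 0))
  # earlier threshold flies earlier where both occur in the same year
  key1 <- unique(paste(em$location, em$year)[em$class == "P1"])
  key2 <- unique(paste(em$location, em$year)[em$class == "P2"])
  for (k in intersect(key1, key2)) {
    sel <- paste(em$location, em$year) == k
    m1 <- median(em$emergence[sel & em$class == "P1"])
    m2 <- median(em$emergence[sel & em$class == "P2"])
    expect_lte(as.numeric(m1), as.numeric(m2))
  }
  # no off-year flight at offYearFraction = 0
  expect_true(all(em$year[em$class == "P2"] == 2018))
})

test_that("trapping respects the genotyping cap and retains season extremes", {
  cfg <- simConfig(nLoci = 20, nPop1 = 200, nPop2 = 0, nF1 = 0, seed = 13)
  st <- simulateStudy(cfg)
  tab <- table(st$samples$location, st$samples$interval, st$samples$year)
  expect_true(all(tab <= cfg$trapCap))
  # earliest and latest emergers per location-season are retained
  em <- st$truth[!is.na(st$truth$emergence), ]
  s0 <- as.Date("2017-06-01"); s1 <- as.Date("2017-09-03")
  em17 <- em[em$year == 2017 & em$emergence >= s0 & em$emergence <= s1, ]
  for (l in unique(em17$location)) {
    el <- em17[em17$location == l, ]
    expect_true(el$id[which.min(el$emergence)] %in% st$samples$id)
    expect_true(el$id[which.max(el$emergence)] %in% st$samples$id)
  }
})

test_that("the full study generator is deterministic given its seed", {
  a <- simulateStudy(simConfig(nLoci = 40, nPop1 = 10, nPop2 = 10, seed = 21))
  b <- simulateStudy(simConfig(nLoci = 40, nPop1 = 10, nPop2 = 10, seed = 21))
  expect_identical(dosage(a$genotypes), dosage(b$genotypes))
  expect_identical(a$samples, b$samples)
  expect_identical(a$temperature, b$temperature)
  c <- simulateStudy(simConfig(nLoci = 40, nPop1 = 10, nPop2 = 10, seed = 22))
  expect_false(identical(dosage(a$genotypes), dosage(c$genotypes)))
})
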