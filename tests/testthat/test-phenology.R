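# grid fixture builder: counts list of per-location data.frames
gridFrom <- function(...) {
  rows <- list(...)
  g <- do.call(rbind, lapply(rows, function(r)
    data.frame(location = r[[1]], year = 2018L, interval = r[[2]],
               date = as.Date("2018-06-10") + 10 * r[[2]],
               nTaxon1 = r[[3]], nTaxon2 = r[[4]])))
  attr(g, "taxa") <- c("A", "B")
  class(g) <- c("CollectionGrid", "data.frame")
  g
}

test_that("presence index matches hand-counted fixtures at both grains", {
  # one location: A in {1,2,3}, B in {3,4} -> both {3}, either {1,2,3,4}
  g <- gridFrom(list("L1", 1:4, c(1, 2, 3, 0), c(0, 0, 1, 2)))
  expect_equal(presenceIndex(g, "by_location")$value, 0.25)
  expect_equal(presenceIndex(g, "pooled")$value, 0.25)

  # loc1: A{1,2}, B{4}; loc2: A{2}, B{2,4}
  g2 <- gridFrom(list("L1", c(1, 2, 4), c(1, 1, 0), c(0, 0, 1)),
                 list("L2", c(2, 4), c(1, 0), c(1, 1)))
  byLoc <- presenceIndex(g2, "by_location")
  expect_equal(unname(byLoc$components), c(0, 0.5))
  expect_equal(byLoc$value, 0.25)
  pooled <- presenceIndex(g2, "pooled")
  expect_equal(pooled$value, 1 / 3)
  expect_equal(pooled$numerator, 1)
  expect_equal(pooled$denominator, 3)

  # identical presence sets -> 1 at both grains
  g3 <- gridFrom(list("L1", 1:2, c(2, 1), c(1, 3)))
  expect_equal(presenceIndex(g3, "by_location")$value, 1)
  expect_equal(presenceIndex(g3, "pooled")$value, 1)
})

test_that("abundance index counts individuals in shared intervals", {
  # (A=3,B=0), (A=2,B=1), (A=0,B=4): shared = 2nd interval -> 3/10
  g <- gridFrom(list("L1", 1:3, c(3, 2, 0), c(0, 1, 4)))
  expect_equal(abundanceIndex(g, "by_location")$value, 0.3)
  expect_equal(abundanceIndex(g, "pooled")$value, 0.3)
  # minority variant counts only the scarcer taxon
  expect_equal(abundanceIndex(g, "pooled", numerator = "minority")$value, 0.1)

  # no shared interval -> 0; all shared -> 1
  g0 <- gridFrom(list("L1", 1:2, c(2, 0), c(0, 3)))
  expect_equal(abundanceIndex(g0, "pooled")$value, 0)
  g1 <- gridFrom(list("L1", 1:2, c(2, 1), c(1, 1)))
  expect_equal(abundanceIndex(g1, "pooled")$value, 1)
})

test_that("indices live in [0,1] and are invariant to taxon relabeling", {
  set.seed(11)
  for (i in 1:10) {
    g <- gridFrom(list("L1", 1:5, rpois(5, 2), rpois(5, 2)),
                  list("L2", 1:5, rpois(5, 1), rpois(5, 3)))
    gSwap <- g
    gSwap$nTaxon1 <- g$nTaxon2; gSwap$nTaxon2 <- g$nTaxon1
    for (grain in c("by_location", "pooled")) {
      p <- presenceIndex(g, grain)$value
      a <- abundanceIndex(g, grain)$value
      if (!is.na(p)) expect_true(p >= 0 && p <= 1)
      if (!is.na(a)) expect_true(a >= 0 && a <= 1)
      expect_equal(p, presenceIndex(gSwap, grain)$value)
      expect_equal(a, abundanceIndex(gSwap, grain)$value)
    }
  }
})

test_that("removing one taxon from shared intervals drives both indices to 0", {
  g <- gridFrom(list("L1", 1:3, c(2, 2, 0), c(0, 1, 3)))
  g$nTaxon2[g$nTaxon1 > 0] <- 0L
  expect_equal(presenceIndex(g, "pooled")$value, 0)
  expect_equal(abundanceIndex(g, "pooled")$value, 0)
})

test_that("the collection grid excludes hybrids and validates intervals", {
  samples <- data.frame(id = c("a", "b", "c", "d"),
                        location = "L1", year = 2018L,
                        interval = c(1L, 1L, 2L, 2L),
                        date = as.Date("2018-06-20") + c(0, 0, 10, 10))
  labels <- c(a = "P1", b = "F1", c = "P2", d = "P1")
  g <- buildGrid(samples, labels, taxa = c("P1", "P2"))
  expect_equal(g$nTaxon1, c(1L, 1L))   # F1 contributes to neither taxon
  expect_equal(g$nTaxon2, c(0L, 1L))

  samples$interval[1] <- NA
  expect_error(buildGrid(samples, labels, taxa = c("P1", "P2")), "interval")
})

test_that("Mann-Whitney U, p and effect sizes match oracles including ties", {
  fs <- function(x, y) {
    s <- data.frame(id = c(paste0("x", seq_along(x)), paste0("y", seq_along(y))),
                    location = "L", year = 2018L, interval = 1L,
                    date = as.Date("2018-01-01") + c(x, y))
    labels <- setNames(rep(c("A", "B"), c(length(x), length(y))), s$id)
    flightSummary(s, labels, c("A", "B"), "date")
  }
  r <- fs(c(1, 2), c(3, 4))
  expect_equal(r$U1, 0)
  expect_equal(r$U2, 4)
  expect_equal(r$rRankBiserial, 1)

  r2 <- fs(c(5, 6, 7), c(5, 6, 7))
  expect_equal(r2$U1, 9 / 2)
  expect_equal(r2$rRankBiserial, 0)

  # tied vectors, n <= 6: exhaustive pair-counting oracle + wilcox.test p
  set.seed(4)
  for (i in 1:20) {
    x <- sample(1:4, sample(2:6, 1), replace = TRUE)
    y <- sample(1:4, sample(2:6, 1), replace = TRUE)
    r3 <- fs(x, y)
    expect_equal(r3$U1, uOracle(x, y))
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(r3$p, wt$p.value, tolerance = 1e-10)
  }
  oneSided <- data.frame(id = c("y1", "y2"), location = "L", year = 2018L,
                         interval = 1L, date = as.Date("2018-01-01") + 1:2)
  expect_error(flightSummary(oneSided, c(y1 = "B", y2 = "B"), c("A", "B")),
               "empty")
})

test_that("staggered local phenologies inflate the pooled-grain index", {
  vals <- vapply(1:3, function(s) {
    st <- simulateStudy(staggeredConfig(seed = s))
    lab <- setNames(st$truth$class, st$truth$id)
    lab[!lab %in% c("P1", "P2")] <- NA
    g <- buildGrid(st$samples, lab, taxa = c("P1", "P2"))
    sym <- st$config$locations$id[st$config$locations$sp1 & st$config$locations$sp2]
    c(presenceIndex(g, "by_location")$value,
      presenceIndex(g, "pooled", locations = sym)$value)
  }, numeric(2))
  expect_gte(mean(vals[2, ]), 3 * mean(vals[1, ]))
})
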