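test_that("VCF genotypes round-trip and GT codes parse correctly", {
  d <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3,
              dimnames = list(NULL, c("s1", "s2")))
  gm <- makeGm(d, pos = c(100, 5100, 20100))
  path <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(gm, path)
  back <- readGenotypeVcf(path)
  expect_equal(unname(dosage(back)), unname(dosage(gm)))
  expect_equal(lociTable(back), lociTable(gm))
  expect_equal(sampleIds(back), sampleIds(gm))
})

test_that("phased, unphased, missing and non-SNP records are handled", {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "s1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t1|1",
    "s1\t200\t.\tA\tT,G\t.\tPASS\t.\tGT\t0/1\t0/0",  # multiallelic: skipped
    "s1\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0",   # indel: skipped
    "s1\t400\t.\tC\tG\t.\tPASS\t.\tGT\t./.\t0|0")
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  expect_message(gm <- readGenotypeVcf(path), "skipped")
  expect_equal(nLoci(gm), 2)
  expect_equal(unname(dosage(gm)[1, ]), c(1L, 2L))   # 0/1 -> 1, 1|1 -> 2
  expect_equal(unname(dosage(gm)[2, ]), c(NA, 0L))   # ./. -> NA
  expect_error(readGenotypeVcf(tempfile()), "not found")
})

test_that("locus filters apply call-rate, MAF and thinning in order", {
  # 4 individuals; locus 1 has 3 calls -> call rate 0.75 < 0.95 -> removed
  d <- rbind(c(0, 1, 1, NA),
             c(0, 0, 0, 1),    # alt freq 1/8 = 0.125 >= 0.10 -> retained
             c(0, 0, 0, 0),    # monomorphic, maf 0 -> removed
             c(1, 1, 0, 2))
  gm <- makeGm(d, pos = c(100, 5100, 6000, 15100))
  out <- filterVariants(gm, 0.95, 0.10, 10000)
  rep <- filterReport(out)
  expect_equal(rep$input, 4)
  expect_equal(rep$removedCallRate, 1)
  expect_equal(rep$removedMaf, 1)
  expect_equal(rep$input, rep$output + rep$removedCallRate + rep$removedMaf +
                 rep$removedThin)
  # after call-rate and MAF, loci at 5100 and 15100 remain: 10000 apart -> both kept
  expect_equal(lociTable(out)$pos, c(5100, 15100))
})

test_that("thinning drops loci under 10 kb and keeps those at exactly 10 kb", {
  d <- matrix(rep(c(0, 1, 1, 2), 3), nrow = 3, byrow = TRUE)
  gm <- makeGm(d, pos = c(100, 5100, 10100))
  out <- filterVariants(gm, 0, 0, 10000)
  expect_equal(lociTable(out)$pos, c(100, 10100))
})

test_that("thinning leaves no same-scaffold pair closer than the window", {
  set.seed(42)
  for (rep in 1:5) {
    L <- 200
    d <- matrix(rbinom(L * 6, 2, 0.4), L)
    scaf <- sample(paste0("s", 1:4), L, replace = TRUE)
    pos <- sample.int(100000, L)
    gm <- GenotypeMatrix(d, data.frame(scaffold = scaf, pos = pos))
    out <- filterVariants(gm, 0, 0, 10000)
    li <- lociTable(out)
    # brute-force all-pairs distance check
    for (s in unique(li$scaffold)) {
      p <- sort(li$pos[li$scaffold == s])
      if (length(p) > 1)
        expect_true(all(diff(p) >= 10000))
    }
    # idempotence
    again <- filterVariants(out, 0, 0, 10000)
    expect_equal(dosage(again), dosage(out))
  }
})

test_that("filtering is idempotent and conserves counts on random fixtures", {
  set.seed(7)
  d <- matrix(rbinom(300 * 8, 2, runif(300, 0.02, 0.5)), 300)
  d[runif(length(d)) < 0.1] <- NA
  gm <- GenotypeMatrix(d, data.frame(
    scaffold = sample(paste0("s", 1:10), 300, TRUE),
    pos = sample.int(500000, 300)))
  f1 <- filterVariants(gm)
  f2 <- filterVariants(f1)
  expect_equal(dosage(f2), dosage(f1))
  r <- filterReport(f1)
  expect_equal(r$input, r$output + r$removedCallRate + r$removedMaf + r$removedThin)
})

test_that("metadata readers validate ids and referential integrity", {
  s <- data.frame(id = c("x1", "x2"), location = c("a", "b"),
                  year = 2018L, interval = 1:2,
                  date = c("2018-06-10", "2018-06-20"), extra = c("u", "v"))
  p <- tempfile(fileext = ".tsv")
  write.table(s, p, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- readSampleTable(p, knownLocations = c("a", "b"))
  expect_s3_class(back$date, "Date")
  expect_equal(back$extra, s$extra)   # unknown columns preserved

  s2 <- s; s2$id <- c("x1", "x1")
  write.table(s2, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleTable(p), "x1")

  write.table(s, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleTable(p, knownLocations = "a"), "b")
})

test_that("temperature and environment tables round-trip", {
  st <- simulateStudy(simConfig(nLoci = 20, nPop1 = 5, nPop2 = 5, seed = 3))
  paths <- writeStudy(st, tempfile("study"))
  tmp <- readTemperatureSeries(paths[["temperature"]])
  expect_equal(nrow(tmp), nrow(st$temperature))
  expect_equal(tmp$tmin, st$temperature$tmin)
  env <- readEnvironmentTable(paths[["environment"]])
  expect_equal(env$location, st$environment$location)
  dup <- env[c(1, 1), ]
  p2 <- tempfile(fileext = ".tsv")
  write.table(dup, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readEnvironmentTable(p2), "duplicated")
})
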