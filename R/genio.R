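#' Read biallelic SNP genotypes from a VCF file
#'
#' Reads GT fields from a VCF v4.x file into a \linkS4class{GenotypeMatrix}.
#' Multiallelic records and non-SNP records (indels, symbolic alleles) are
#' skipped with a message giving the count.  Phased (\code{|}) and unphased
#' (\code{/}) genotypes are treated identically; any genotype containing a
#' missing allele is recorded as NA.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeVcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snp))
    message(sum(!snp), " multiallelic/non-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[snp, , drop = FALSE]
  alleles <- gsub("[/|]", "", gt)
  dos <- nchar(gsub("[^1]", "", alleles))
  dos[!grepl("^[01]+$", alleles) | is.na(gt)] <- NA
  mode(dos) <- "integer"
  loci <- data.frame(scaffold = fix[snp, "CHROM"],
                     pos = as.integer(fix[snp, "POS"]),
                     ref = ref[snp], alt = alt[snp],
                     stringsAsFactors = FALSE)
  GenotypeMatrix(dos, loci)
}

#' Write a GenotypeMatrix as a minimal VCF (GT only)
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGenotypeVcf <- function(x, path) {
  li <- lociTable(x)
  d <- dosage(x)
  gtStr <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow(d))
  gtStr[is.na(d)] <- "./."
  body <- cbind(li$scaffold, li$pos, paste0(li$scaffold, ":", li$pos),
                li$ref, li$alt, ".", "PASS", ".", "GT", gtStr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sampleIds(x)), collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Filter SNPs by call rate, minor allele frequency and physical distance
#'
#' Applies the study's three locus filters in order: (1) keep loci with call
#' rate >= \code{callRateMin}; (2) keep loci with minor-allele frequency >=
#' \code{mafMin}, computed over non-missing calls of all individuals pooled;
#' (3) within each scaffold, scan loci in position order and drop any locus
#' closer than \code{thinBp} to the last retained locus.  The filter report
#' (counts removed by each step) is stored in \code{metadata(x)$filterReport}
#' and retrievable with [filterReport()].  The operation is idempotent.
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param callRateMin minimum fraction of non-missing calls per locus
#'   (default 0.95).
#' @param mafMin minimum minor-allele frequency (default 0.10).
#' @param thinBp minimum distance in bp between retained loci on the same
#'   scaffold (default 10000).
#' @return the filtered \linkS4class{GenotypeMatrix}; zero loci surviving is
#'   returned as an (empty) object, not an error.
#' @export
filterVariants <- function(x, callRateMin = 0.95, mafMin = 0.10,
                           thinBp = 10000) {
  stopifnot(callRateMin >= 0, callRateMin <= 1, mafMin >= 0, mafMin <= 0.5,
            thinBp >= 0)
  d <- dosage(x)
  nIn <- nrow(d)
  callRate <- rowMeans(!is.na(d))
  keep1 <- callRate >= callRateMin
  x1 <- x[keep1, ]
  d1 <- d[keep1, , drop = FALSE]
  af <- rowMeans(d1, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep2 <- !is.na(maf) & maf >= mafMin
  x2 <- x1[keep2, ]
  li <- lociTable(x2)
  keep3 <- logical(nrow(li))
  for (s in unique(li$scaffold)) {
    idx <- which(li$scaffold == s)
    idx <- idx[order(li$pos[idx])]
    last <- -Inf
    for (i in idx) {
      if (li$pos[i] - last >= thinBp) { keep3[i] <- TRUE; last <- li$pos[i] }
    }
  }
  out <- x2[keep3, ]
  rep <- list(input = nIn,
              removedCallRate = sum(!keep1),
              removedMaf = sum(!keep2),
              removedThin = sum(!keep3),
              output = sum(keep3),
              callRateMin = callRateMin, mafMin = mafMin, thinBp = thinBp)
  stopifnot(rep$input == rep$output + rep$removedCallRate + rep$removedMaf +
              rep$removedThin)
  md <- S4Vectors::metadata(out)
  md$filterReport <- rep
  S4Vectors::metadata(out) <- md
  if (rep$output == 0) message("no loci survive filtering")
  out
}

#' @rdname filterVariants
#' @return \code{filterReport}: the report list (counts in/out and removed
#'   per filter), or NULL if \code{x} was never filtered.
#' @export
filterReport <- function(x) S4Vectors::metadata(x)$filterReport

#' Read per-individual sample metadata
#'
#' TSV with header; required columns \code{id}, \code{location},
#' \code{year}, \code{interval}, \code{date}.  Dates are parsed ISO-8601;
#' unknown columns are preserved.  Duplicated ids are an error naming the
#' offenders; if \code{knownLocations} is supplied, samples at unlisted
#' locations are an error naming the locations.
#'
#' @param path TSV path.
#' @param knownLocations optional character vector for referential checks.
#' @return data.frame SampleTable.
#' @export
readSampleTable <- function(path, knownLocations = NULL) {
  s <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("id", "location", "year", "interval", "date")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dup <- unique(s$id[duplicated(s$id)])
  if (length(dup)) stop("duplicated sample id(s): ", paste(dup, collapse = ", "))
  s$date <- as.Date(s$date)
  if (!is.null(knownLocations)) {
    bad <- setdiff(unique(s$location), knownLocations)
    if (length(bad)) stop("unknown location(s): ", paste(bad, collapse = ", "))
  }
  s
}

#' Read a daily temperature series
#'
#' CSV with header: \code{location}, \code{date} (ISO-8601),
#' \code{tmin_c}, \code{tmax_c}, \code{source} ("logger" or "station").
#'
#' @param path CSV path.
#' @return data.frame with columns location, date, tmin, tmax, source.
#' @export
readTemperatureSeries <- function(path) {
  t <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  need <- c("location", "date", "tmin_c", "tmax_c", "source")
  miss <- setdiff(need, names(t))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data.frame(location = t$location, date = as.Date(t$date),
             tmin = t$tmin_c, tmax = t$tmax_c, source = t$source,
             stringsAsFactors = FALSE)
}

#' Read a per-location environment table
#'
#' TSV keyed by \code{location}; all other columns are treated as
#' environmental variables.  Duplicated locations are an error.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readEnvironmentTable <- function(path) {
  e <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"location" %in% names(e)) stop("missing column: location")
  dup <- unique(e$location[duplicated(e$location)])
  if (length(dup)) stop("duplicated location(s): ", paste(dup, collapse = ", "))
  e
}
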