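test_that("VCF genotypes are coded as ALT-allele counts, missing as NA", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", "b", "c", "d", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "./.", sep = "\t")), path)
  ds <- read_vcf(path)
  expect_equal(unname(ds$calls[, 1]), c(0L, 1L, 2L, NA))
  expect_equal(ds$map$id, "rs1")
})

test_that("empty VCF body yields a valid zero-variant dataset", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "a", sep = "\t")), path)
  ds <- suppressWarnings(read_vcf(path))
  expect_equal(n_variants <- ncol(ds$calls), 0L)
})

test_that("unsorted VCF positions raise an error naming the culprit", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", sep = "\t"),
    paste("1", "200", ".", "A", "G", ".", ".", ".", "GT", "0/0", sep = "\t"),
    paste("1", "100", ".", "A", "G", ".", ".", ".", "GT", "0/0", sep = "\t")),
    path)
  expect_error(read_vcf(path), "1:100")
})

test_that("multiallelic records error unless skipped", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", sep = "\t"),
    paste("1", "100", ".", "A", "G,T", ".", ".", ".", "GT", "0/1", sep = "\t"),
    paste("1", "200", ".", "A", "G", ".", ".", ".", "GT", "1/1", sep = "\t")),
    path)
  expect_error(read_vcf(path), "multiallelic")
  ds <- read_vcf(path, skip_multiallelic = TRUE)
  expect_equal(ncol(ds$calls), 1L)
  expect_equal(unname(ds$calls[1, 1]), 2L)
})

test_that("VCF and PLINK round-trips reproduce the dataset exactly", {
  pr <- planted_fixture(n_ind = 10)
  td <- withr::local_tempdir()
  vcf <- file.path(td, "g.vcf")
  write_vcf(pr$ds, vcf)
  back <- read_vcf(vcf)
  expect_identical(back$calls, pr$ds$calls)
  expect_identical(back$haps, pr$ds$haps)
  expect_equal(back$map$pos_bp, pr$ds$map$pos_bp)

  write_plink_text(pr$ds, file.path(td, "g"))
  back2 <- read_plink_text(file.path(td, "g.ped"), file.path(td, "g.map"),
                           counted_alleles = pr$ds$map$alt)
  expect_identical(unname(back2$calls), unname(pr$ds$calls))
})

test_that("PLINK allele coding counts the chosen allele and honours 0 0 missing", {
  td <- withr::local_tempdir()
  writeLines("1 snp1 0 100", file.path(td, "x.map"))
  writeLines(c("F a 0 0 0 -9 A A",
               "F b 0 0 0 -9 A G",
               "F c 0 0 0 -9 0 0"), file.path(td, "x.ped"))
  ds <- read_plink_text(file.path(td, "x.ped"), file.path(td, "x.map"),
                        counted_alleles = "G")
  expect_equal(unname(ds$calls[, 1]), c(0L, 1L, NA))
})

test_that("pedigree reading topologically sorts, adds missing founders, rejects cycles", {
  td <- withr::local_tempdir()
  writeLines(c("C,A,B", "A,0,0", "B,0,0"), file.path(td, "ped.csv"))
  ped <- read_pedigree(file.path(td, "ped.csv"))
  expect_equal(nrow(ped), 3L)
  expect_gt(match("C", ped$id), max(match(c("A", "B"), ped$id)))

  writeLines(c("A,B,0", "B,A,0"), file.path(td, "cycle.csv"))
  expect_error(read_pedigree(file.path(td, "cycle.csv")), "cycle")

  # referenced-but-unlisted parents are auto-added as founders
  writeLines(c("X,P,Q"), file.path(td, "orphan.csv"))
  expect_warning(ped2 <- read_pedigree(file.path(td, "orphan.csv")), "founder")
  expect_setequal(ped2$id, c("P", "Q", "X"))
})

test_that("a multi-generation full-sib loop pedigree is accepted with 2 founders", {
  ped <- as_pedigree(data.frame(
    id = c("A", "B", "C", "D", "E", "F", "G", "H"),
    sire = c(NA, NA, "A", "A", "C", "C", "E", "E"),
    dam = c(NA, NA, "B", "B", "D", "D", "F", "F")))
  expect_equal(sum(is.na(ped$sire) & is.na(ped$dam)), 2L)
  expect_equal(nrow(ped), 8L)
})

test_that("filter_variants applies the MAF, call-rate and chromosome rules", {
  # site 1: MAF 0.04 (dropped); site 2: clean MAF 0.5 (kept);
  # site 3: call rate 0.24 (dropped at > 0.30)
  n <- 50
  calls <- cbind(
    c(rep(1L, 4), rep(0L, n - 4)),
    rep(c(0L, 2L), n / 2),
    c(rep(1L, 12), rep(NA, n - 12)))
  ds <- calls_ds(calls)
  out <- filter_variants(ds, maf_min = 0.05, sample_genotyped_min = 0.30)
  expect_equal(out$map$id, "snp2")
  log <- attr(out, "qc_log")
  expect_equal(log$n_pass[log$rule == "kept"], 1L)
})

test_that("filter_variants survivor count matches an independent recount and is idempotent", {
  set.seed(42)
  n <- 40; m <- 400
  calls <- matrix(rbinom(n * m, 2, rep(runif(m, 0.01, 0.5), each = n)),
                  nrow = n)
  calls[matrix(runif(n * m) < 0.4, n)] <- NA
  ds <- calls_ds(calls)
  out <- suppressWarnings(filter_variants(ds, 0.05, 0.30))
  # brute-force recount
  keep <- vapply(seq_len(m), function(j) {
    x <- calls[, j]; x <- x[!is.na(x)]
    if (!length(x)) return(FALSE)
    p <- sum(x) / (2 * length(x))
    min(p, 1 - p) >= 0.05 && length(x) / n > 0.30
  }, TRUE)
  expect_equal(ncol(out$calls), sum(keep))
  twice <- suppressWarnings(filter_variants(out, 0.05, 0.30))
  expect_identical(twice$calls, out$calls)
})

test_that("BED export is 0-based half-open and round-trips exactly", {
  td <- withr::local_tempdir()
  path <- file.path(td, "iv.bed")
  iv <- tibble::tibble(chrom = "chr1", start_bp = 1L, end_bp = 100L)
  write_bed(iv, path)
  expect_equal(readLines(path), "chr1\t0\t100")
  back <- read_bed(path)
  expect_equal(back$start_bp, iv$start_bp)
  expect_equal(back$end_bp, iv$end_bp)

  write_bed(iv[0, ], path)
  expect_equal(file.size(path), 0)
  expect_equal(nrow(read_bed(path)), 0L)

  # interval lengths preserved for a realistic island list
  isl <- tibble::tibble(chrom = c("3", "10", "13"),
                        start_bp = c(35000000L, 1200000L, 140000000L),
                        end_bp = c(38620000L, 1200090L, 141300000L))
  write_bed(isl, path)
  back <- read_bed(path)
  expect_equal(back$end_bp - back$start_bp, isl$end_bp - isl$start_bp)
})
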