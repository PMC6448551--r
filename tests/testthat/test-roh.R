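# a clean background genotype vector with heterozygote-rich flanks
noisy_background <- function(n, seed) {
  set.seed(seed)
  sample(c(0L, 1L, 2L), n, replace = TRUE, prob = c(0.3, 0.4, 0.3))
}

test_that("a long homozygous run becomes exactly one segment; short runs are filtered", {
  # 150 homozygous SNPs spanning ~2 Mb inside het-rich flanks
  flank <- 200
  spacing <- 13600
  g <- c(noisy_background(flank, 1), rep(2L, 150), noisy_background(flank, 2))
  ds <- calls_ds(matrix(g, nrow = 1), spacing_bp = spacing)
  roh <- call_roh(ds)
  expect_equal(nrow(roh), 1L)
  expect_gte(roh$n_snps[1], 150)
  expect_equal(as.data.frame(roh), as.data.frame(call_roh_exact(ds)))

  # same run on a denser map spanning only 0.9 Mb: killed by the length filter
  g2 <- c(noisy_background(flank, 3), rep(2L, 150), noisy_background(flank, 4))
  ds2 <- calls_ds(matrix(g2, nrow = 1), spacing_bp = 6000)   # 150 SNPs ~ 0.9 Mb
  expect_equal(nrow(call_roh(ds2)), 0L)
})

test_that("the window het allowance tolerates an isolated heterozygote in a planted tract", {
  pr <- planted_fixture(fraction = 0.12, n_ind = 10, seed = 9)
  clean <- call_roh(pr$ds)
  # flip one homozygous call in the middle of the largest segment
  big <- clean[which.max(clean$length_bp), ]
  i <- match(big$sample, pr$ds$samples)
  mid <- (big$start_bp + big$end_bp) / 2
  j <- which.min(abs(pr$ds$map$pos_bp - mid))
  noisy <- pr$ds
  noisy$calls[i, j] <- 1L
  after <- call_roh(noisy)
  hit <- after[after$sample == big$sample & after$chrom == big$chrom &
                 after$start_bp <= mid & after$end_bp >= mid, ]
  expect_equal(nrow(hit), 1L)
})

test_that("degenerate inputs: all-het individual empty, all-hom chromosome one full segment", {
  m <- 300
  ds_het <- calls_ds(matrix(1L, 1, m))
  expect_equal(nrow(call_roh(ds_het)), 0L)
  expect_equal(nrow(call_roh_exact(ds_het)), 0L)

  ds_hom <- calls_ds(matrix(2L, 1, m))
  r <- call_roh(ds_hom)
  expect_equal(nrow(r), 1L)
  expect_equal(r$start_bp, ds_hom$map$pos_bp[1])
  expect_equal(r$end_bp, ds_hom$map$pos_bp[m])
  expect_equal(r$n_snps, m)
  expect_equal(as.data.frame(r), as.data.frame(call_roh_exact(ds_hom)))
})

test_that("fast caller equals the brute-force oracle across random planted datasets", {
  for (s in 1:8) {
    ds <- tiny_population(n_ind = 15, n_chrom = 2, chrom_mb = 25,
                          seed = 100 + s)
    pr <- plant_roh(ds, runif(1, 0.05, 0.3), seed = 200 + s)
    expect_equal(as.data.frame(call_roh(pr$ds)),
                 as.data.frame(call_roh_exact(pr$ds)),
                 info = paste("seed", s))
  }
})

test_that("every emitted segment satisfies the length, count and density filters", {
  pr <- planted_fixture(fraction = 0.2, n_ind = 20, seed = 5)
  noisy <- inject_noise(pr$ds, miss_rate = 0.02, het_error_rate = 0.002,
                        seed = 6)
  p <- roh_params()
  roh <- call_roh(noisy, p)
  expect_gt(nrow(roh), 0)
  expect_true(all(roh$length_bp == roh$end_bp - roh$start_bp + 1))
  expect_true(all(roh$n_snps >= p$min_snps))
  expect_true(all(roh$length_bp >= p$min_length_kb * 1000))
  expect_true(all(roh$length_bp / roh$n_snps <= p$max_kb_per_snp * 1000))
  # non-overlapping and sorted within sample x chromosome
  by <- split(as.data.frame(roh), paste(roh$sample, roh$chrom))
  for (g in by) {
    if (nrow(g) > 1) expect_true(all(g$start_bp[-1] > g$end_bp[-nrow(g)]))
  }
})

test_that("tightening parameters never grows the calls", {
  pr <- planted_fixture(fraction = 0.2, n_ind = 15, seed = 7)
  noisy <- inject_noise(pr$ds, miss_rate = 0.02, het_error_rate = 0.002,
                        seed = 8)
  base <- call_roh(noisy, roh_params())
  longer <- call_roh(noisy, roh_params(min_length_kb = 2000))
  expect_lte(nrow(longer), nrow(base))
  stricter <- suppressWarnings(call_roh(noisy, roh_params(window_max_het = 0)))
  expect_lte(sum(stricter$length_bp), sum(base$length_bp))
})

test_that("called segments recover planted tracts with few false positives", {
  ds <- tiny_population(n_ind = 20, n_chrom = 3, chrom_mb = 50, seed = 11)
  pr <- plant_roh(ds, 0.15, mean_length_mb = 4, length_dist = "fixed",
                  seed = 12)
  roh <- call_roh(pr$ds)
  covered <- 0; planted <- 0; called_total <- sum(roh$length_bp)
  for (r in seq_len(nrow(pr$truth))) {
    tr <- pr$truth[r, ]
    planted <- planted + tr$end_bp - tr$start_bp + 1
    seg <- roh[roh$sample == tr$sample & roh$chrom == tr$chrom, ]
    if (!nrow(seg)) next
    ov <- pmin(seg$end_bp, tr$end_bp) - pmax(seg$start_bp, tr$start_bp) + 1
    covered <- covered + sum(pmax(ov, 0))
  }
  expect_gte(covered / planted, 0.99)
  # the background population carries genuine LD-induced homozygous runs that
  # the caller rightly reports; the false-positive bound is on what planting
  # adds beyond the planted tracts and that background
  background <- sum(call_roh(ds)$length_bp)
  false_len <- called_total - covered - background
  expect_lte(false_len / (ds$l_auto_bp * 20), 0.02)
})

test_that("class summaries and expected ROH lengths follow the arithmetic", {
  tab <- roh_class_arithmetic(
    n = c(14524, 2753, 1413, 18690),
    mean_length_mb = c(2.31, 6.85, 17.24, 4.11),
    l_auto_bp = 2.26e9, n_samples = 202,
    labels = c("1-5 Mb", "5-10 Mb", ">10 Mb", "Total"))
  expect_equal(tab$percent[1:3], c(77.71, 14.73, 7.56), tolerance = 1e-4)
  expect_equal(tab$percent[4], 100)

  empty <- call_roh(calls_ds(matrix(1L, 2, 300)))
  s <- summarize_roh(empty, l_auto_bp = 1e8, n_samples = 2)
  expect_true(all(s$n == 0))
  expect_true(all(s$coverage_pct == 0))

  expect_equal(expected_roh_length(50), 1)
  expect_equal(expected_roh_length(5), 10)
  expect_equal(expected_roh_length(1e9), 0, tolerance = 1e-6)
  expect_equal(expected_roh_length(50, cm_per_mb = 2), 0.5)
})

test_that("a chromosome shorter than the window is skipped with a warning", {
  calls <- matrix(2L, 2, 30)
  ds <- calls_ds(calls)
  expect_warning(r <- call_roh(ds), "skipped")
  expect_equal(nrow(r), 0L)
})
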