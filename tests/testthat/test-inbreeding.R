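test_that("f_ped reproduces classical coefficients and the path-counting oracle", {
  ped <- as_pedigree(data.frame(
    id = c("A", "B", "C", "D", "FS"),
    sire = c(NA, NA, "A", "A", "C"),
    dam = c(NA, NA, "B", "B", "D")))
  f <- f_ped(ped)
  expect_equal(f$f_ped[f$sample == "A"], 0)           # founder
  expect_equal(f$f_ped[f$sample == "FS"], 0.25)       # full-sib offspring

  # half-sib offspring: shared sire A, unrelated dams
  ped_hs <- as_pedigree(data.frame(
    id = c("A", "B", "M", "C", "D", "X"),
    sire = c(NA, NA, NA, "A", "A", "C"),
    dam = c(NA, NA, NA, "B", "M", "D")))
  expect_equal(f_ped(ped_hs, "X")$f_ped, 0.125)

  # parent-offspring mating
  ped_po <- as_pedigree(data.frame(
    id = c("A", "B", "C", "X"),
    sire = c(NA, NA, "A", "A"), dam = c(NA, NA, "B", "C")))
  expect_equal(f_ped(ped_po, "X")$f_ped, 0.25)

  # deeper looped pedigree against the independent path-counting oracle
  ped_deep <- as_pedigree(data.frame(
    id = c("A", "B", "C", "D", "E", "F", "G", "H"),
    sire = c(NA, NA, "A", "A", "C", "C", "E", "E"),
    dam = c(NA, NA, "B", "B", "D", "D", "F", "F")))
  got <- f_ped(ped_deep)
  for (id in ped_deep$id) {
    expect_equal(got$f_ped[got$sample == id], path_f(ped_deep, id),
                 info = id, tolerance = 1e-12)
  }
  expect_error(f_ped(ped_deep, "nobody"), "not in pedigree")
})

test_that("f_roh is additive across length classes and handles the extremes", {
  pr <- planted_fixture(fraction = 0.2, n_ind = 15, seed = 13)
  roh <- call_roh(pr$ds)
  fr <- f_roh(roh)
  expect_identical(fr$f_roh_all,
                   fr$f_roh_1_5 + fr$f_roh_5_10 + fr$f_roh_gt10)
  expect_true(all(fr$f_roh_all >= 0 & fr$f_roh_all <= 1))

  # no segments -> 0
  empty <- call_roh(calls_ds(matrix(1L, 2, 300)))
  fr0 <- f_roh(empty, l_auto_bp = 1e8)
  expect_true(all(fr0$f_roh_all == 0))

  # synthetic whole-genome segment -> f_roh_all = 1
  ds1 <- calls_ds(matrix(2L, 1, 300))
  r1 <- call_roh(ds1)
  fr1 <- f_roh(r1)
  expect_equal(fr1$f_roh_all, 1)
})

test_that("f_snp matches per-formula hand arithmetic", {
  # 10 samples at one SNP with p = 0.5 (plus a companion SNP to stay polymorphic)
  calls <- cbind(c(rep(0L, 5), rep(2L, 5)), rep(c(0L, 1L, 2L, 1L, 0L), 2))
  ds <- calls_ds(calls)
  # sample 1: fully homozygous at both SNPs? sample 1 has calls (0, 0): yes
  fs <- f_snp(ds)
  expect_equal(fs$f_snp2[1], 1)   # no heterozygous call: homozygosity excess = 1

  # single-SNP terms at Y = 1, p = 0.5: SNP1 term 0, SNP2 term -1, SNP3 term -1
  p <- 0.5; h <- 2 * p * (1 - p); Y <- 1
  expect_equal((Y - 2 * p)^2 / h - 1, -1)        # estimator 1 with the -1
  expect_equal(1 - Y * (2 - Y) / h, -1)
  expect_equal((Y^2 - Y * (1 + 2 * p) + 2 * p^2) / h, -1)
  # a purely heterozygous sample across p = 0.5 SNPs hits those values
  calls2 <- matrix(c(0L, 1L, 2L, 1L), nrow = 4, ncol = 6)
  ds2 <- calls_ds(calls2)
  fs2 <- f_snp(ds2)
  expect_equal(fs2$f_snp2[fs2$sample == "s2"], -1)
  expect_equal(fs2$f_snp3[fs2$sample == "s2"], -1)
})

test_that("all three SNP estimators are unbiased under Hardy-Weinberg sampling", {
  set.seed(31)
  n <- 500; m <- 5000
  p <- runif(m, 0.05, 0.5)
  calls <- vapply(p, function(pp) rbinom(n, 2, pp), integer(n))
  ds <- calls_ds(calls)
  fs <- f_snp(ds)
  expect_lt(abs(mean(fs$f_snp1)), 0.01)
  expect_lt(abs(mean(fs$f_snp2)), 0.01)
  expect_lt(abs(mean(fs$f_snp3)), 0.01)
})

test_that("genomic estimators track planted autozygosity; F_SNP2 tracks F_ROH best", {
  ds <- tiny_population(n_ind = 40, n_chrom = 3, chrom_mb = 50, seed = 17)
  # wide F spread: per-individual target fractions from 0 to 0.35
  fracs <- seq(0, 0.35, length.out = 40)
  planted <- ds
  truths <- numeric(40)
  for (i in seq_len(40)) {
    one <- geno_ds(ds$samples[i], ds$map,
                   ds$calls[i, , drop = FALSE], l_auto_bp = ds$l_auto_bp,
                   haps = ds$haps[c(2 * i - 1, 2 * i), , drop = FALSE])
    pr <- plant_roh(one, fracs[i], seed = 300 + i)
    planted$calls[i, ] <- pr$ds$calls
    planted$haps[c(2 * i - 1, 2 * i), ] <- pr$ds$haps
    truths[i] <- pr$f_true$f_true
  }
  roh <- call_roh(planted)
  tab <- inbreeding_table(ds = planted, roh = roh)
  expect_gt(cor(truths, tab$f_roh_all), 0.9)

  cm <- inbreeding_correlations(tab)
  expect_true(isSymmetric(unclass(cm)))
  expect_true(all(diag(unclass(cm)) == 1))
  # the homozygosity-excess estimator tracks F_ROH far better than the
  # additive-variance one; under error-free, uniform-MAF simulation F_SNP2
  # and F_SNP3 are nearly collinear, so F_SNP2 ties for best rather than
  # strictly dominating as in empirical sequence data
  r_with_froh <- unclass(cm)["f_roh_all", c("f_snp1", "f_snp2", "f_snp3")]
  expect_gt(r_with_froh["f_snp2"], r_with_froh["f_snp1"])
  expect_gt(r_with_froh["f_snp3"], r_with_froh["f_snp1"])
  expect_lt(abs(r_with_froh["f_snp2"] - r_with_froh["f_snp3"]), 0.02)
})
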