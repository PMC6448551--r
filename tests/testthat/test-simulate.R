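test_that("founder pools are reproducible and respect the LD dial", {
  map <- sim_map(1, 3e7, 13600)
  p1 <- sample_founders(50, map, seed = 7)
  p2 <- sample_founders(50, map, seed = 7)
  expect_identical(p1$haplotypes, p2$haplotypes)

  # rho = 0: adjacent sites essentially uncorrelated
  p0 <- sample_founders(100, map, rho = 0, seed = 8)
  H <- p0$haplotypes
  r <- cor(as.vector(H[, -ncol(H)]), as.vector(H[, -1]))
  expect_lt(abs(r), 0.05)

  # rho = 0.95: strong adjacent LD decaying with distance
  p95 <- sample_founders(100, map, rho = 0.95, seed = 9)
  H <- p95$haplotypes
  adj_r2 <- vapply(seq_len(300), function(j) cor(H[, j], H[, j + 1])^2, 0)
  far_r2 <- vapply(seq_len(300), function(j) cor(H[, j], H[, j + 100])^2, 0)
  expect_gt(mean(adj_r2, na.rm = TRUE), mean(far_r2, na.rm = TRUE))
})

test_that("gene_drop recovers classical autozygosity expectations", {
  m2 <- sim_map(1, 1e8, 5e5)   # 1 chromosome of 1 Morgan at 1 cM/Mb
  pool <- sample_founders(5, m2, seed = 4)

  # offspring of two unrelated founders carries no IBD tract
  ped_u <- as_pedigree(data.frame(id = c("A", "B", "X"),
                                  sire = c(NA, NA, "A"), dam = c(NA, NA, "B")))
  gd <- gene_drop(ped_u, pool, seed = 11)
  expect_equal(gd$f_true$f_true[gd$f_true$sample == "X"], 0)

  # selfing: E[f_true] = 1/2
  ped_s <- as_pedigree(data.frame(id = c("F", "S"),
                                  sire = c(NA, "F"), dam = c(NA, "F")))
  set.seed(21)
  fs <- replicate(150, gene_drop(ped_s, pool)$f_true$f_true[2])
  expect_lt(abs(mean(fs) - 0.5), 0.05)

  # full-sib offspring: E[f_true] = 1/4, matching f_ped on the same pedigree
  ped_fs <- as_pedigree(data.frame(
    id = c("A", "B", "C", "D", "X"),
    sire = c(NA, NA, "A", "A", "C"), dam = c(NA, NA, "B", "B", "D")))
  set.seed(22)
  ff <- replicate(150, gene_drop(ped_fs, pool)$f_true$f_true[5])
  expect_lt(abs(mean(ff) - f_ped(ped_fs, "X")$f_ped), 0.05)
})

test_that("gene_drop truth tracts and genotypes are consistent", {
  ped <- as_pedigree(data.frame(
    id = c("A", "B", "C", "D", "X"),
    sire = c(NA, NA, "A", "A", "C"), dam = c(NA, NA, "B", "B", "D")))
  map <- sim_map(2, 3e7, 13600)
  pool <- sample_founders(10, map, seed = 5)
  gd <- gene_drop(ped, pool, seed = 31)
  tr <- gd$truth
  for (r in seq_len(nrow(tr))) {
    i <- match(tr$sample[r], gd$ds$samples)
    idx <- which(gd$ds$map$chrom == tr$chrom[r] &
                   gd$ds$map$pos_bp >= tr$start_bp[r] &
                   gd$ds$map$pos_bp <= tr$end_bp[r])
    expect_true(all(gd$ds$calls[i, idx] != 1L))
  }
  # tracts non-overlapping within an individual
  by_ind <- split(tr, paste(tr$sample, tr$chrom))
  for (g in by_ind) {
    g <- g[order(g$start_bp), ]
    if (nrow(g) > 1) expect_true(all(g$start_bp[-1] > g$end_bp[-nrow(g)]))
  }
  expect_error(gene_drop(ped[0, ], pool), "empty")
})

test_that("plant_roh hits its target fraction and degenerate fractions behave", {
  ds <- tiny_population(n_ind = 20, n_chrom = 3, chrom_mb = 50, seed = 2)
  p0 <- plant_roh(ds, 0, seed = 1)
  expect_identical(p0$ds$calls, ds$calls)
  expect_equal(nrow(p0$truth), 0L)

  p1 <- plant_roh(ds, 1, seed = 1)
  expect_true(all(p1$ds$calls != 1L))

  pr <- plant_roh(ds, 0.168, seed = 4)
  expect_lt(abs(mean(pr$f_true$f_true) - 0.168), 0.02)
  # every site inside a planted tract is homozygous
  r <- 1L
  i <- match(pr$truth$sample[r], ds$samples)
  idx <- which(ds$map$chrom == pr$truth$chrom[r] &
                 ds$map$pos_bp >= pr$truth$start_bp[r] &
                 ds$map$pos_bp <= pr$truth$end_bp[r])
  expect_true(all(pr$ds$calls[i, idx] %in% c(0L, 2L)))
})

test_that("plant_sweep makes carriers identical over the core and is detectable by EHH", {
  map <- sim_map(1, 3e7, 13600)
  pool <- sample_founders(40, map, seed = 6)
  sw <- plant_sweep(pool, focal = 1100, carrier_freq = 0.5,
                    core_half_len_bp = 2e6, seed = 7)
  ds <- assemble_population(sw$pool, 40, seed = 8)
  # identical carriers: EHH of the derived allele stays 1 within +/- 1 Mb
  e <- ehh(ds, 1100, 1)
  within <- abs(e$pos_bp - map$pos_bp[1100]) <= 1e6
  expect_true(all(e$ehh[within] == 1))

  # zero core length only rewrites the focal column
  sw0 <- plant_sweep(pool, 1100, 0.5, 0, seed = 7)
  expect_identical(sw0$pool$haplotypes[, -1100], pool$haplotypes[, -1100])
})

test_that("inject_noise hits its rates and zero rates are the identity", {
  ds <- tiny_population(n_ind = 30, seed = 3)
  expect_identical(inject_noise(ds, 0, 0, seed = 1)$calls, ds$calls)
  noisy <- inject_noise(ds, miss_rate = 0.02, seed = 2)
  frac <- mean(is.na(noisy$calls))
  n_calls <- length(ds$calls)
  expect_lt(abs(frac - 0.02), 3 * sqrt(0.02 * 0.98 / n_calls) + 1e-9)
})
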