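#' Observed and expected heterozygosity
#'
#' Per SNP: observed heterozygosity Ho is the fraction of non-missing calls
#' equal to 1; expected heterozygosity He is `2 p (1 - p)` with `p` the
#' allele frequency from non-missing calls. Genome-wide values are the
#' unweighted mean and sd across SNPs (see [glance.rohscan_het()]).
#'
#' @param ds A [geno_ds] with at least one variant.
#' @return A tibble of class `rohscan_het`: chrom, pos_bp, id, n_called, p,
#'   ho, he. All-missing SNPs are excluded with a warning.
#' @export
heterozygosity <- function(ds) {
  if (n_variants(ds) == 0L) abort("dataset has no variants")
  n_called <- colSums(!is.na(ds$calls))
  if (any(n_called == 0)) {
    warn(sprintf("%d all-missing SNP(s) excluded from heterozygosity",
                 sum(n_called == 0)))
  }
  keep <- n_called > 0
  p <- allele_freq(ds)[keep]
  ho <- unname(colMeans(ds$calls[, keep, drop = FALSE] == 1L, na.rm = TRUE))
  out <- tibble::tibble(chrom = ds$map$chrom[keep], pos_bp = ds$map$pos_bp[keep],
                        id = ds$map$id[keep], n_called = n_called[keep],
                        p = p, ho = ho, he = 2 * p * (1 - p))
  class(out) <- c("rohscan_het", class(out))
  out
}

#' @rdname heterozygosity
#' @param x A `rohscan_het` table.
#' @param ... Unused.
#' @return For `glance()`: a one-row tibble with ho_mean, ho_sd, he_mean,
#'   he_sd, n_snps.
#' @export
glance.rohscan_het <- function(x, ...) {
  tibble::tibble(ho_mean = mean(x$ho), ho_sd = sd(x$ho),
                 he_mean = mean(x$he), he_sd = sd(x$he), n_snps = nrow(x))
}

#' Pairwise linkage disequilibrium (composite r-squared)
#'
#' r² between two SNPs is the squared Pearson correlation of their
#' genotype-count vectors over samples non-missing at both sites — the
#' composite (haplotype-free) LD measure appropriate to unphased genotypes.
#' Pairs are enumerated within chromosomes up to `max_dist_bp` apart; pairs
#' involving a zero-variance site are skipped.
#'
#' @param ds A [geno_ds] with at least 2 SNPs on some chromosome.
#' @param max_dist_bp Maximum pair distance (default 10 Mb).
#' @param max_pairs_per_snp Optional cap on partners per left SNP (random
#'   subsample, seeded) to bound runtime on dense maps.
#' @param seed Seed for the optional subsample.
#' @return Tibble: chrom, pos1, pos2, dist_bp, r2.
#' @export
ld_r2 <- function(ds, max_dist_bp = 1e7, max_pairs_per_snp = NULL,
                  seed = NULL) {
  out <- list()
  with_seed(seed, {
    for (chrom in unique(ds$map$chrom)) {
      idx <- which(ds$map$chrom == chrom)
      if (length(idx) < 2L) next
      pos <- ds$map$pos_bp[idx]
      G <- ds$calls[, idx, drop = FALSE]
      v <- apply(G, 2, function(x) stats::var(x, na.rm = TRUE))
      jmax <- findInterval(pos + max_dist_bp, pos)
      for (a in seq_along(idx)) {
        if (a + 1L > jmax[a] || is.na(v[a]) || v[a] == 0) next
        partners <- (a + 1L):jmax[a]
        partners <- partners[!is.na(v[partners]) & v[partners] > 0]
        if (!length(partners)) next
        if (!is.null(max_pairs_per_snp) && length(partners) > max_pairs_per_snp) {
          partners <- sort(sample(partners, max_pairs_per_snp))
        }
        r <- unname(suppressWarnings(
          cor(G[, a], G[, partners, drop = FALSE],
              use = "pairwise.complete.obs"))[1, ])
        ok <- !is.na(r)
        if (!any(ok)) next
        out[[length(out) + 1L]] <- tibble::tibble(
          chrom = chrom, pos1 = pos[a], pos2 = pos[partners][ok],
          dist_bp = pos[partners][ok] - pos[a], r2 = r[ok]^2)
      }
    }
  })
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), pos1 = integer(),
                          pos2 = integer(), dist_bp = integer(), r2 = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Sample-size adjustment of r-squared
#'
#' Subtracts the finite-sample expectation of composite r² under no linkage,
#' `1 / (beta * n)`, flooring at 0: `beta = 2` for unphased genotype data on
#' `n` diploid samples, `beta = 1` for haplotype data.
#'
#' @param r2 Raw r² value(s).
#' @param n_samples Number of samples (>= 2).
#' @param beta Ploidy/phase factor (2 = unphased genotypes, 1 = haplotypes).
#' @return Adjusted r², floored at 0.
#' @export
r2_adjust <- function(r2, n_samples, beta = 2) {
  stopifnot(n_samples >= 2, beta %in% c(1, 2))
  pmax(0, r2 - 1 / (beta * n_samples))
}

#' Bin LD pairs by physical distance
#'
#' Aggregates an [ld_r2()] pair table into distance bins, attaching the mean
#' raw r², the sample-size-adjusted mean (via [r2_adjust()]), the pair count,
#' and the recombination fraction `c_t` assigned to the bin midpoint via
#' [physical_to_c()]. This is the input of [ne_trajectory()].
#'
#' @param pairs An [ld_r2()] table.
#' @param n_samples Number of samples behind the r² values.
#' @param breaks_bp Bin edges in bp; default 50 log-spaced bins over
#'   50 kb – 10 Mb.
#' @param beta Passed to [r2_adjust()].
#' @param cm_per_mb,mapping Passed to [physical_to_c()].
#' @return Tibble of class `ld_bins`: dist_lo, dist_hi, dist_mid, n_pairs,
#'   mean_r2, mean_r2adj, c_t.
#' @export
bin_ld <- function(pairs, n_samples,
                   breaks_bp = exp(seq(log(5e4), log(1e7), length.out = 51)),
                   beta = 2, cm_per_mb = 1,
                   mapping = c("haldane", "sved", "linear")) {
  mapping <- match.arg(mapping)
  bin <- cut(pairs$dist_bp, breaks = breaks_bp, include.lowest = TRUE)
  mids <- (head(breaks_bp, -1) + tail(breaks_bp, -1)) / 2
  out <- tibble::tibble(dist_lo = head(breaks_bp, -1),
                        dist_hi = tail(breaks_bp, -1), dist_mid = mids,
                        bin = levels(bin)) |>
    dplyr::left_join(
      tibble::tibble(bin = as.character(bin), r2 = pairs$r2) |>
        dplyr::filter(!is.na(.data$bin)) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n_pairs = dplyr::n(), mean_r2 = mean(.data$r2),
                         .groups = "drop"),
      by = "bin") |>
    dplyr::mutate(n_pairs = dplyr::coalesce(.data$n_pairs, 0L),
                  mean_r2adj = r2_adjust(.data$mean_r2, n_samples, beta),
                  c_t = physical_to_c(.data$dist_mid, cm_per_mb, mapping)) |>
    dplyr::select(-"bin")
  attr(out, "n_samples") <- n_samples
  attr(out, "beta") <- beta
  class(out) <- c("ld_bins", class(out))
  out
}
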