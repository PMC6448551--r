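# EHH decay on one side of a core SNP among the carrier haplotypes of one
# core allele. Haplotype classes are refined marker by marker; EHH at marker
# x is the probability that two random carriers are identical from the core
# through x: sum over classes of choose(n_h, 2) / choose(n_c, 2).
# Returns recorded points (marker index, ehh) and whether the chromosome end
# was reached while EHH was still at or above the cutoff.
ehh_side <- function(H, rows, j_core, j_stop, step, cutoff) {
  nc <- length(rows)
  denom <- nc * (nc - 1) / 2
  grp <- rep(1L, nc)
  js <- integer(0); es <- numeric(0)
  truncated <- FALSE
  j <- j_core
  repeat {
    j <- j + step
    if ((step > 0 && j > j_stop) || (step < 0 && j < j_stop)) {
      truncated <- TRUE
      break
    }
    grp <- grp * 2L + H[rows, j]
    grp <- match(grp, unique(grp))
    cnt <- tabulate(grp)
    e <- sum(cnt * (cnt - 1) / 2) / denom
    js <- c(js, j); es <- c(es, e)
    if (e < cutoff) break
  }
  list(j = js, ehh = es, truncated = truncated)
}

#' Extended haplotype homozygosity around a core SNP
#'
#' EHH at distance x from the core, among the carriers of one core allele, is
#' the probability that two randomly drawn carrier haplotypes are identical
#' over the whole stretch from the core to x. It equals 1 at the core and
#' decays (non-increasingly) outward; the curve is truncated once EHH drops
#' below `ehh_cutoff` or a chromosome end is reached (the latter flagged).
#'
#' @param ds A phased [geno_ds] (or any object with `haps` and `map`).
#' @param core_snp Marker index of the core SNP.
#' @param core_allele 0 or 1: the core allele whose carriers are followed.
#' @param ehh_cutoff Truncation level (default 0.05).
#' @return Tibble: pos_bp, side ("left"/"core"/"right"), ehh; attribute
#'   `truncated` (named logical, per side).
#' @export
ehh <- function(ds, core_snp, core_allele, ehh_cutoff = 0.05) {
  if (is.null(ds$haps)) abort("EHH needs phased haplotypes")
  H <- ds$haps
  map <- ds$map
  rows <- which(H[, core_snp] == core_allele)
  if (length(rows) < 2L) abort("fewer than 2 carriers of the core allele")
  on <- which(map$chrom == map$chrom[core_snp])
  left <- ehh_side(H, rows, core_snp, min(on), -1L, ehh_cutoff)
  right <- ehh_side(H, rows, core_snp, max(on), 1L, ehh_cutoff)
  out <- tibble::tibble(
    pos_bp = c(rev(map$pos_bp[left$j]), map$pos_bp[core_snp], map$pos_bp[right$j]),
    side = c(rep("left", length(left$j)), "core", rep("right", length(right$j))),
    ehh = c(rev(left$ehh), 1, right$ehh))
  attr(out, "truncated") <- c(left = left$truncated, right = right$truncated)
  out
}

# integrated EHH (Morgan) for one allele at one core; trapezoid over genetic
# distance, from the core (EHH = 1) outward through every recorded point
# (including the first sub-cutoff point).
ihh_one <- function(H, rows, j_core, on, pos_gen, cutoff) {
  if (length(rows) < 2L) return(list(ihh = NA_real_, truncated = NA))
  area <- 0
  trunc <- FALSE
  for (step in c(-1L, 1L)) {
    side <- ehh_side(H, rows, j_core, if (step < 0) min(on) else max(on),
                     step, cutoff)
    e <- c(1, side$ehh)
    g <- c(pos_gen[j_core], pos_gen[side$j])
    if (length(g) > 1) {
      area <- area + sum((head(e, -1) + tail(e, -1)) / 2 * abs(diff(g)))
    }
    trunc <- trunc || side$truncated
  }
  list(ihh = area, truncated = trunc)
}

#' Genome-wide iHS scan
#'
#' For every scanned SNP the EHH curves of the ancestral and derived alleles
#' are integrated over genetic distance (trapezoid rule, truncation at
#' `ehh_cutoff`) into iHH_A and iHH_D, and the unstandardized score is
#' `ln(iHH_A / iHH_D)`. Scores are then standardized to mean 0 and sd 1
#' within derived-allele-frequency bins of width `bin_width`, so that
#' standardized scores are comparable across frequencies and follow an
#' approximate standard normal under neutrality. The two-sided normal
#' p-value is reported as `p_ihs = -log10(1 - 2 |Phi(iHS) - 0.5|)`.
#'
#' Ancestral alleles come from the map's `anc` column where set; SNPs
#' without an ancestral call fall back to treating the major allele as
#' ancestral, with a warning.
#'
#' @param ds A phased [geno_ds].
#' @param maf_min SNPs with derived-allele frequency outside
#'   `[maf_min, 1 - maf_min]` are skipped.
#' @param bin_width Width of the derived-allele-frequency standardization bins.
#' @param cm_per_mb Genetic distance per physical distance (cM/Mb).
#' @param ehh_cutoff EHH truncation level.
#' @param exclude_truncated Drop SNPs whose EHH hit a chromosome end before
#'   the cutoff (default TRUE).
#' @return Tibble of class `ihs_result`: chrom, pos_bp, id, freq_derived,
#'   ihh_a, ihh_d, ihs_raw, ihs_std, p_ihs, flag ("ok", "truncated",
#'   "zero_ihh", "skipped_freq", "few_carriers").
#' @export
ihs_scan <- function(ds, maf_min = 0.05, bin_width = 0.05, cm_per_mb = 1,
                     ehh_cutoff = 0.05, exclude_truncated = TRUE) {
  if (is.null(ds$haps)) abort("iHS needs phased haplotypes")
  H <- ds$haps
  map <- ds$map
  m <- nrow(map)
  anc_is_ref <- ifelse(is.na(map$anc), NA, map$anc == map$ref)
  anc_is_alt <- ifelse(is.na(map$anc), NA, map$anc == map$alt)
  known <- !is.na(anc_is_ref) & (anc_is_ref | anc_is_alt)
  freq1 <- colMeans(H)
  # ancestral allele in 0/1 haplotype coding (0 = ref, 1 = alt)
  anc_allele <- integer(m)
  anc_allele[known] <- ifelse(anc_is_ref[known], 0L, 1L)
  if (any(!known)) {
    warn(sprintf(
      "%d SNP(s) lack an ancestral allele: falling back to the major allele as ancestral",
      sum(!known)))
    anc_allele[!known] <- ifelse(freq1[!known] > 0.5, 1L, 0L)
  }
  der_allele <- 1L - anc_allele
  freq_derived <- ifelse(der_allele == 1L, freq1, 1 - freq1)
  pos_gen <- map$pos_bp * cm_per_mb / 1e8   # Morgans
  res <- tibble::tibble(chrom = map$chrom, pos_bp = map$pos_bp, id = map$id,
                        freq_derived = freq_derived, ihh_a = NA_real_,
                        ihh_d = NA_real_, ihs_raw = NA_real_,
                        ihs_std = NA_real_, p_ihs = NA_real_, flag = "ok")
  res$flag[freq_derived < maf_min | freq_derived > 1 - maf_min] <- "skipped_freq"
  for (chrom in unique(map$chrom)) {
    on <- which(map$chrom == chrom)
    for (j in on) {
      if (res$flag[j] != "ok") next
      rows_a <- which(H[, j] == anc_allele[j])
      rows_d <- which(H[, j] == der_allele[j])
      if (length(rows_a) < 2L || length(rows_d) < 2L) {
        res$flag[j] <- "few_carriers"
        next
      }
      a <- ihh_one(H, rows_a, j, on, pos_gen, ehh_cutoff)
      d <- ihh_one(H, rows_d, j, on, pos_gen, ehh_cutoff)
      res$ihh_a[j] <- a$ihh
      res$ihh_d[j] <- d$ihh
      if (isTRUE(a$truncated) || isTRUE(d$truncated)) {
        res$flag[j] <- "truncated"
        if (exclude_truncated) next
      }
      if (is.na(a$ihh) || is.na(d$ihh) || a$ihh == 0 || d$ihh == 0) {
        res$flag[j] <- "zero_ihh"
        next
      }
      res$ihs_raw[j] <- log(a$ihh / d$ihh)
    }
  }
  usable <- !is.na(res$ihs_raw) &
    (res$flag == "ok" | (!exclude_truncated & res$flag == "truncated"))
  bins <- floor(res$freq_derived / bin_width)
  tab <- table(bins[usable])
  moments <- lapply(names(tab)[tab >= 2L], function(b) {
    in_bin <- usable & bins == as.numeric(b)
    list(b = as.numeric(b), mu = mean(res$ihs_raw[in_bin]),
         s = sd(res$ihs_raw[in_bin]))
  })
  moments <- purrr::keep(moments, ~ .x$s > 0)
  if (length(moments)) {
    centers <- vapply(moments, `[[`, 0, "b")
    for (b in unique(bins[usable])) {
      in_bin <- usable & bins == b
      # bins with < 2 usable SNPs borrow the nearest populated bin's moments
      mm <- moments[[which.min(abs(centers - b))]]
      res$ihs_std[in_bin] <- (res$ihs_raw[in_bin] - mm$mu) / mm$s
    }
  }
  res$p_ihs <- ifelse(is.na(res$ihs_std), NA_real_, p_ihs(res$ihs_std))
  class(res) <- c("ihs_result", class(res))
  res
}

#' -log10 two-sided normal p-value of a standardized score
#'
#' `p_ihs = -log10(1 - 2 |Phi(z) - 0.5|)`, i.e. the -log10 of the two-sided
#' standard-normal p-value of `z`; 0 at z = 0 and about 2.30 at |z| = 2.81.
#'
#' @param z Standardized iHS score(s).
#' @return -log10 p-value(s).
#' @export
p_ihs <- function(z) {
  -log10(2 * pnorm(abs(z), lower.tail = FALSE))
}

#' Two-sided significance threshold on the standard-normal scale
#'
#' The |z| cutoff whose two-sided normal p-value equals `p_two_sided`:
#' `qnorm(1 - p/2)`. At p = 0.005 this is 2.81 — the conventional iHS
#' significance threshold matching a top-0.5% selection.
#'
#' @param p_two_sided Two-sided p-value in `(0, 1]`.
#' @return The |z| threshold.
#' @export
significance_threshold <- function(p_two_sided) {
  stopifnot(all(p_two_sided > 0), all(p_two_sided <= 1))
  qnorm(1 - p_two_sided / 2)
}

#' Fill island mean |iHS| and correlate incidence with |iHS|
#'
#' Fills each island's `mean_abs_ihs` with the mean absolute standardized
#' iHS of the SNPs it spans.
#'
#' @param islands A [detect_islands()] table.
#' @param ihs An [ihs_scan()] result.
#' @return The islands tibble with `mean_abs_ihs` filled.
#' @export
island_ihs_summary <- function(islands, ihs) {
  islands$mean_abs_ihs <- vapply(seq_len(nrow(islands)), function(r) {
    z <- ihs$ihs_std[ihs$chrom == islands$chrom[r] &
                       ihs$pos_bp >= islands$start_bp[r] &
                       ihs$pos_bp <= islands$end_bp[r]]
    if (all(is.na(z))) NA_real_ else mean(abs(z), na.rm = TRUE)
  }, 0)
  islands
}

#' Pearson correlation of ROH incidence with |iHS|
#'
#' @param track A [snp_roh_incidence()] track.
#' @param ihs An [ihs_scan()] result on the same map.
#' @return The Pearson correlation over SNPs with both values.
#' @export
incidence_ihs_cor <- function(track, ihs) {
  j <- dplyr::inner_join(
    tibble::tibble(chrom = track$chrom, pos_bp = track$pos_bp,
                   proportion = track$proportion),
    tibble::tibble(chrom = ihs$chrom, pos_bp = ihs$pos_bp,
                   abs_ihs = abs(ihs$ihs_std)),
    by = c("chrom", "pos_bp"))
  cor(j$proportion, j$abs_ihs, use = "complete.obs")
}
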