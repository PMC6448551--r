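#' Parameters of the sliding-window ROH caller
#'
#' Defaults reproduce the PLINK v1.07 `--homozyg` defaults commonly used with
#' sequence-derived SNP panels: a 50-SNP scanning window allowing 1
#' heterozygous and 5 missing calls, a 5% homozygous-window hit fraction for
#' SNP eligibility, and segment filters of at least 100 SNPs, at least 1 Mb,
#' at most 50 kb per SNP, with runs split at gaps over 1000 kb. A minimum
#' length of 1 Mb at ~1 cM/Mb captures inbreeding up to roughly 50 ancestral
#' generations (see [expected_roh_length()]).
#'
#' @param window_snps Scanning window size in SNPs.
#' @param window_max_het Maximum heterozygous calls for a window to count as
#'   homozygous.
#' @param window_max_missing Maximum missing calls per homozygous window.
#' @param window_hit_fraction Minimum fraction of a SNP's spanning windows that
#'   must be homozygous for the SNP to be ROH-eligible.
#' @param min_snps Minimum SNPs per emitted segment.
#' @param min_length_kb Minimum segment length (kb).
#' @param max_kb_per_snp Maximum segment kb per SNP (density filter).
#' @param max_gap_kb Maximum gap (kb) between consecutive eligible SNPs within
#'   one segment.
#' @return A `roh_params` list.
#' @export
roh_params <- function(window_snps = 50, window_max_het = 1,
                       window_max_missing = 5, window_hit_fraction = 0.05,
                       min_snps = 100, min_length_kb = 1000,
                       max_kb_per_snp = 50, max_gap_kb = 1000) {
  p <- list(window_snps = window_snps, window_max_het = window_max_het,
            window_max_missing = window_max_missing,
            window_hit_fraction = window_hit_fraction, min_snps = min_snps,
            min_length_kb = min_length_kb, max_kb_per_snp = max_kb_per_snp,
            max_gap_kb = max_gap_kb)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && v >= 0,
                       TRUE)),
            p$window_hit_fraction > 0, p$window_hit_fraction <= 1,
            p$window_snps >= 1, p$min_snps >= 1, p$min_length_kb > 0,
            p$max_kb_per_snp > 0, p$max_gap_kb > 0)
  structure(p, class = "roh_params")
}

# turn a logical eligibility vector + positions into filtered segments
eligible_to_segments <- function(eligible, pos, params) {
  if (!any(eligible)) return(NULL)
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- list()
  for (k in runs) {
    i <- starts[k]:ends[k]
    # split at physical gaps between consecutive eligible SNPs
    gap <- diff(pos[i]) > params$max_gap_kb * 1000
    grp <- cumsum(c(0L, gap))
    for (g in split(i, grp)) {
      n_snps <- length(g)
      len <- pos[g[n_snps]] - pos[g[1]] + 1
      if (n_snps >= params$min_snps &&
          len >= params$min_length_kb * 1000 &&
          len / n_snps <= params$max_kb_per_snp * 1000) {
        out <- c(out, list(c(start_bp = pos[g[1]], end_bp = pos[g[n_snps]],
                             n_snps = n_snps, length_bp = len)))
      }
    }
  }
  if (!length(out)) return(NULL)
  tibble::as_tibble(do.call(rbind, out))
}

roh_length_class <- function(length_bp, edges_mb = c(1, 5, 10, Inf)) {
  labs <- paste0(
    head(edges_mb, -1), "-",
    ifelse(is.finite(tail(edges_mb, -1)), tail(edges_mb, -1), ""), " Mb")
  labs[length(labs)] <- paste0(">", edges_mb[length(edges_mb) - 1], " Mb")
  cut(length_bp / 1e6, breaks = edges_mb, labels = labs, right = FALSE)
}

new_roh_set <- function(segments, ds, params) {
  segments <- segments %||%
    tibble::tibble(sample = character(), chrom = character(),
                   start_bp = numeric(), end_bp = numeric(),
                   n_snps = numeric(), length_bp = numeric())
  segments$length_class <- roh_length_class(segments$length_bp)
  segments <- dplyr::arrange(segments, match(.data$sample, ds$samples),
                             .data$chrom, .data$start_bp)
  structure(segments,
            class = c("roh_set", class(tibble::tibble())),
            samples = ds$samples, l_auto_bp = ds$l_auto_bp, params = params)
}

#' Call runs of homozygosity
#'
#' Sliding-window ROH detection on a genotype dataset, per individual and
#' chromosome: (a) every `window_snps`-SNP window is scored homozygous when it
#' holds at most `window_max_het` heterozygous and `window_max_missing`
#' missing calls; (b) a SNP is ROH-eligible when at least
#' `window_hit_fraction` of the windows that contain it are homozygous (SNPs
#' near chromosome ends are judged on the windows that exist); (c) maximal
#' runs of eligible SNPs, split at physical gaps over `max_gap_kb`, become
#' candidate segments whose endpoints are the first and last eligible SNP;
#' (d) candidates must carry at least `min_snps` SNPs, span at least
#' `min_length_kb`, and average at most `max_kb_per_snp` per SNP.
#'
#' @param ds A [geno_ds] with variants sorted by position (enforced).
#' @param params A [roh_params()] list.
#' @return A `roh_set`: tibble of segments (sample, chrom, start_bp, end_bp,
#'   n_snps, length_bp, length_class) with the calling parameters, sample
#'   list, and `l_auto_bp` attached as attributes.
#' @export
call_roh <- function(ds, params = roh_params()) {
  w <- params$window_snps
  idx_by_chrom <- split(seq_len(n_variants(ds)), ds$map$chrom)
  short <- names(idx_by_chrom)[lengths(idx_by_chrom) < w]
  if (length(short)) {
    warn(sprintf("chromosome(s) with fewer than %d SNPs skipped: %s",
                 w, paste(short, collapse = ", ")))
    idx_by_chrom <- idx_by_chrom[lengths(idx_by_chrom) >= w]
  }
  segs <- list()
  for (chrom in names(idx_by_chrom)) {
    idx <- idx_by_chrom[[chrom]]
    pos <- ds$map$pos_bp[idx]
    n <- length(idx)
    nw <- n - w + 1L
    for (i in seq_len(n_samples(ds))) {
      g <- ds$calls[i, idx]
      het <- !is.na(g) & g == 1L
      mis <- is.na(g)
      hom_win <- roll_sum(het, w) <= params$window_max_het &
        roll_sum(mis, w) <= params$window_max_missing
      # windows containing SNP j start in [max(1, j-w+1), min(j, nw)]
      cs <- c(0, cumsum(hom_win))
      a <- pmax(seq_len(n) - w + 1L, 1L)
      b <- pmin(seq_len(n), nw)
      n_hom <- cs[b + 1L] - cs[a]
      eligible <- n_hom / (b - a + 1L) >= params$window_hit_fraction
      s <- eligible_to_segments(eligible, pos, params)
      if (!is.null(s)) {
        segs <- c(segs, list(dplyr::mutate(s, sample = ds$samples[i],
                                           chrom = chrom, .before = 1)))
      }
    }
  }
  new_roh_set(if (length(segs)) dplyr::bind_rows(segs) else NULL, ds, params)
}

#' Brute-force oracle for the ROH caller
#'
#' Recomputes the same windowed definition as [call_roh()] by direct
#' enumeration — per SNP, every spanning window is re-scored by explicitly
#' counting its heterozygous and missing calls — with run construction and
#' filtering written independently of the optimized path. Exists for testing:
#' its output must equal [call_roh()] exactly on any dataset.
#'
#' @inheritParams call_roh
#' @return A `roh_set`.
#' @export
call_roh_exact <- function(ds, params = roh_params()) {
  w <- params$window_snps
  segs <- list()
  for (chrom in unique(ds$map$chrom)) {
    idx <- which(ds$map$chrom == chrom)
    n <- length(idx)
    if (n < w) {
      warn(sprintf("chromosome(s) with fewer than %d SNPs skipped: %s", w, chrom))
      next
    }
    pos <- ds$map$pos_bp[idx]
    nw <- n - w + 1L
    for (i in seq_len(n_samples(ds))) {
      g <- ds$calls[i, idx]
      # each row of embed() is one window's calls, summed explicitly
      het_w <- rowSums(embed(as.integer(!is.na(g) & g == 1L), w))
      mis_w <- rowSums(embed(as.integer(is.na(g)), w))
      win_hom <- het_w <= params$window_max_het &
        mis_w <= params$window_max_missing
      # explicit membership table: row j lists the hom status of the w
      # windows whose start could cover SNP j, NA where no such window exists
      ps <- c(rep(NA_real_, w - 1L), as.numeric(win_hom), rep(NA_real_, w - 1L))
      eligible <- rowMeans(embed(ps, w), na.rm = TRUE) >=
        params$window_hit_fraction
      # independent run construction: walk the vector
      j <- 1L
      while (j <= n) {
        if (!eligible[j]) { j <- j + 1L; next }
        k <- j
        while (k < n && eligible[k + 1L] &&
               pos[k + 1L] - pos[k] <= params$max_gap_kb * 1000) k <- k + 1L
        n_snps <- k - j + 1L
        len <- pos[k] - pos[j] + 1
        if (n_snps >= params$min_snps && len >= params$min_length_kb * 1000 &&
            len / n_snps <= params$max_kb_per_snp * 1000) {
          segs <- c(segs, list(tibble::tibble(
            sample = ds$samples[i], chrom = chrom, start_bp = pos[j],
            end_bp = pos[k], n_snps = n_snps, length_bp = len)))
        }
        j <- k + 1L
      }
    }
  }
  new_roh_set(if (length(segs)) dplyr::bind_rows(segs) else NULL, ds, params)
}

#' Summarize ROH by length class
#'
#' Per-class descriptive statistics in the layout of a classical ROH summary
#' table: segment count, percent of the total count, mean and standard
#' deviation of segment length (Mb), and genome coverage — the summed class
#' length as a percentage of `n_samples * l_auto_bp`. A `Total` row covers
#' all segments.
#'
#' @param roh A `roh_set` from [call_roh()].
#' @param class_edges_mb Length-class edges in Mb.
#' @param l_auto_bp,n_samples Override the values recorded on the `roh_set`.
#' @return A tibble: length_class, n, percent, mean_length_mb, sd_length_mb,
#'   coverage_pct.
#' @export
summarize_roh <- function(roh, class_edges_mb = c(1, 5, 10, Inf),
                          l_auto_bp = NULL, n_samples = NULL) {
  l_auto_bp <- l_auto_bp %||% attr(roh, "l_auto_bp")
  n_samples <- n_samples %||% length(attr(roh, "samples"))
  cls <- roh_length_class(roh$length_bp, class_edges_mb)
  levs <- levels(cls)
  per <- purrr::map_dfr(levs, function(lv) {
    len <- roh$length_bp[!is.na(cls) & cls == lv] / 1e6
    tibble::tibble(length_class = lv, n = length(len),
                   mean_length_mb = if (length(len)) mean(len) else NA_real_,
                   sd_length_mb = if (length(len) > 1) sd(len) else NA_real_)
  })
  all_len <- roh$length_bp / 1e6
  tot <- tibble::tibble(length_class = "Total", n = nrow(roh),
                        mean_length_mb = if (nrow(roh)) mean(all_len) else NA_real_,
                        sd_length_mb = if (nrow(roh) > 1) sd(all_len) else NA_real_)
  out <- dplyr::bind_rows(per, tot)
  roh_class_arithmetic(out$n, out$mean_length_mb, l_auto_bp, n_samples,
                       total_n = nrow(roh), labels = out$length_class,
                       sd_length_mb = out$sd_length_mb)
}

#' ROH class-table arithmetic from counts and mean lengths
#'
#' The arithmetic core of [summarize_roh()], exposed so that a class table can
#' be reconstructed from published per-class counts and mean lengths alone:
#' percent of count = `n / total * 100`; genome coverage (%) =
#' `n * mean_length / (n_samples * l_auto) * 100`.
#'
#' @param n Per-class segment counts (the last element may be a Total row).
#' @param mean_length_mb Per-class mean segment lengths (Mb).
#' @param l_auto_bp Autosome length (bp).
#' @param n_samples Number of individuals.
#' @param total_n Denominator for the percent column; defaults to `n` of a
#'   final `Total` row when labels mark one, else `sum(n)`.
#' @param labels Optional class labels.
#' @param sd_length_mb Optional per-class sd column, carried through.
#' @return Tibble: length_class, n, percent, mean_length_mb, sd_length_mb,
#'   coverage_pct.
#' @export
roh_class_arithmetic <- function(n, mean_length_mb, l_auto_bp, n_samples,
                                 total_n = NULL, labels = NULL,
                                 sd_length_mb = NA_real_) {
  labels <- labels %||% as.character(seq_along(n))
  total_n <- total_n %||%
    if (tolower(labels[length(labels)]) == "total") n[length(n)] else sum(n)
  tibble::tibble(
    length_class = labels,
    n = n,
    percent = if (total_n > 0) n / total_n * 100 else rep(0, length(n)),
    mean_length_mb = mean_length_mb,
    sd_length_mb = sd_length_mb,
    coverage_pct = ifelse(n > 0, n * mean_length_mb * 1e6 /
                            (n_samples * l_auto_bp) * 100, 0)
  )
}

#' Expected ROH length for an ancestor depth
#'
#' The expected length of an autozygous segment descending from a common
#' ancestor `g` generations back is `1 / (2 g)` Morgan; converted to Mb at
#' `cm_per_mb`. At 1 cM/Mb, 50 generations give 1 Mb and 5 generations give
#' 10 Mb — the rationale for the 1 Mb minimum length and for mapping ROH
#' length classes to generation depths.
#'
#' @param g Generations to the common ancestor (> 0).
#' @param cm_per_mb Genetic map density (cM per Mb).
#' @return Expected length in Mb.
#' @export
expected_roh_length <- function(g, cm_per_mb = 1) {
  stopifnot(all(g > 0), cm_per_mb > 0)
  (1 / (2 * g)) * 100 / cm_per_mb
}
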