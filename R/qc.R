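#' Marker quality control
#'
#' Keeps variants passing three filters: minor allele frequency at least
#' `maf_min` (computed from non-missing calls), per-variant call rate strictly
#' greater than `sample_genotyped_min`, and chromosome in `autosomes`. Variant
#' order is preserved and the operation is idempotent.
#'
#' The call-rate rule is applied per variant (fraction of samples genotyped at
#' the marker); a per-sample call-rate report is attached for inspection since
#' permissive thresholds like 30% usually signal reduced-representation data
#' where per-sample missingness varies widely.
#'
#' @param ds A [geno_ds].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param sample_genotyped_min Minimum fraction of samples genotyped, exclusive
#'   bound (default 0.30).
#' @param autosomes Character vector of chromosome labels to keep; `NULL`
#'   keeps all chromosomes in the map.
#' @return A filtered [geno_ds] with attributes `qc_log` (tibble of per-rule
#'   drop counts) and `sample_call_rate` (per-sample genotyping rate).
#' @export
filter_variants <- function(ds, maf_min = 0.05, sample_genotyped_min = 0.30,
                            autosomes = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 1,
            sample_genotyped_min >= 0, sample_genotyped_min <= 1)
  p <- allele_freq(ds)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  call_rate <- colMeans(!is.na(ds$calls))
  chrom_ok <- if (is.null(autosomes)) rep(TRUE, n_variants(ds))
              else ds$map$chrom %in% as.character(autosomes)
  maf_ok <- maf >= maf_min
  rate_ok <- call_rate > sample_genotyped_min
  keep <- maf_ok & rate_ok & chrom_ok
  if (!any(keep) && n_variants(ds) > 0) {
    warn("no variants pass QC; returning an empty dataset")
  }
  out <- subset_variants(ds, keep)
  attr(out, "qc_log") <- tibble::tibble(
    rule = c("maf", "call_rate", "chromosome", "kept"),
    n_fail = c(sum(!maf_ok), sum(!rate_ok), sum(!chrom_ok), NA_integer_),
    n_pass = c(sum(maf_ok), sum(rate_ok), sum(chrom_ok), sum(keep))
  )
  attr(out, "sample_call_rate") <- tibble::tibble(
    sample = ds$samples,
    call_rate = rowMeans(!is.na(ds$calls))
  )
  out
}
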