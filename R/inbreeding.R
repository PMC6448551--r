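#' Pedigree inbreeding coefficients
#'
#' F of an individual is the kinship of its parents, computed by the
#' recursive (tabular) kinship method with memoization:
#' `kinship(a, a) = (1 + F(a)) / 2` and
#' `kinship(a, b) = (kinship(father(a), b) + kinship(mother(a), b)) / 2`,
#' descending the younger individual; an unknown parent contributes 0.
#'
#' @param ped A `pedigree` (topologically sorted; see [as_pedigree()]).
#' @param ids Individuals to evaluate; defaults to all pedigree members.
#' @return Tibble with columns `sample` and `f_ped`.
#' @export
f_ped <- function(ped, ids = NULL) {
  ids <- ids %||% ped$id
  missing_ids <- setdiff(ids, ped$id)
  if (length(missing_ids)) {
    abort(paste("id(s) not in pedigree:", paste(missing_ids, collapse = ", ")))
  }
  ord <- stats::setNames(seq_len(nrow(ped)), ped$id)
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)
  memo <- new.env(parent = emptyenv())
  kin <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- if (ord[[a]] <= ord[[b]]) paste(a, b) else paste(b, a)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (a == b) {
      0.5 * (1 + kin(sire[[a]], dam[[a]]))
    } else {
      # descend the younger (later in topological order) of the pair
      y <- if (ord[[a]] >= ord[[b]]) a else b
      o <- if (identical(y, a)) b else a
      0.5 * (kin(sire[[y]], o) + kin(dam[[y]], o))
    }
    memo[[key]] <- val
    val
  }
  tibble::tibble(sample = ids,
                 f_ped = unname(vapply(ids, function(x) kin(sire[[x]], dam[[x]]), 0)))
}

#' ROH-based inbreeding coefficients by length class
#'
#' F_ROH = L_ROH / L_auto: the summed length of an individual's ROH segments
#' divided by the mapped autosome length, overall and within each length
#' class. The overall coefficient is computed as the sum of the class
#' coefficients, so additivity holds to machine precision.
#'
#' @param roh A `roh_set` from [call_roh()].
#' @param l_auto_bp Autosome length; defaults to the value on the `roh_set`.
#' @param class_edges_mb Length-class edges in Mb (default 1, 5, 10, Inf).
#' @return Tibble: sample, f_roh_1_5, f_roh_5_10, f_roh_gt10, f_roh_all (one
#'   row per sample in the originating dataset, zero where no segments).
#' @export
f_roh <- function(roh, l_auto_bp = NULL, class_edges_mb = c(1, 5, 10, Inf)) {
  l_auto_bp <- l_auto_bp %||% attr(roh, "l_auto_bp")
  samples <- attr(roh, "samples") %||% unique(roh$sample)
  cls <- roh_length_class(roh$length_bp, class_edges_mb)
  levs <- levels(cls)
  wide <- tibble::tibble(sample = roh$sample, cls = cls, len = roh$length_bp) |>
    dplyr::filter(!is.na(.data$cls)) |>
    dplyr::group_by(.data$sample, .data$cls) |>
    dplyr::summarise(f = sum(.data$len) / l_auto_bp, .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cls", values_from = "f")
  out <- tibble::tibble(sample = samples) |>
    dplyr::left_join(wide, by = "sample")
  for (lv in levs) if (!lv %in% names(out)) out[[lv]] <- 0
  out <- dplyr::mutate(out, dplyr::across(-"sample", ~ dplyr::coalesce(.x, 0)))
  cols <- stats::setNames(levs, c("f_roh_1_5", "f_roh_5_10", "f_roh_gt10"))
  res <- tibble::tibble(sample = out$sample)
  for (nm in names(cols)) res[[nm]] <- out[[cols[[nm]]]]
  res$f_roh_all <- res$f_roh_1_5 + res$f_roh_5_10 + res$f_roh_gt10
  res
}

#' SNP-by-SNP inbreeding estimators
#'
#' The three marker-based estimators, with `Y` the counted-allele copies at a
#' SNP, `p` its frequency in the current sample, and `h = 2 p (1 - p)`:
#' \describe{
#'   \item{F_SNP1}{variance of additive genotypes:
#'     `mean((Y - 2p)^2 / h) - 1`}
#'   \item{F_SNP2}{homozygosity excess: `1 - mean(Y (2 - Y) / h)`}
#'   \item{F_SNP3}{correlation of uniting gametes:
#'     `mean((Y^2 - Y (1 + 2p) + 2 p^2) / h)`}
#' }
#' Means run over a sample's non-missing calls at polymorphic SNPs
#' (monomorphic SNPs are excluded everywhere — `h = 0`). Because frequencies
#' come from the current population the estimators can take negative values.
#'
#' @param ds A [geno_ds].
#' @param estimators Which of the three to compute (subset of 1:3).
#' @return Tibble: sample, f_snp1, f_snp2, f_snp3 (requested columns), plus
#'   `n_snps_used` — the per-sample count of usable SNPs. Samples with zero
#'   usable SNPs get `NA` and a warning.
#' @export
f_snp <- function(ds, estimators = 1:3) {
  stopifnot(all(estimators %in% 1:3))
  p <- allele_freq(ds)
  poly <- !is.nan(p) & p > 0 & p < 1
  Y <- ds$calls[, poly, drop = FALSE]
  p <- p[poly]
  h <- 2 * p * (1 - p)
  n_used <- rowSums(!is.na(Y))
  if (any(n_used == 0)) {
    warn(sprintf("%d sample(s) have no usable SNPs; estimators set to NA",
                 sum(n_used == 0)))
  }
  P <- matrix(p, nrow = nrow(Y), ncol = length(p), byrow = TRUE)
  H <- matrix(h, nrow = nrow(Y), ncol = length(p), byrow = TRUE)
  out <- tibble::tibble(sample = ds$samples)
  if (1 %in% estimators) {
    out$f_snp1 <- unname(rowMeans((Y - 2 * P)^2 / H, na.rm = TRUE)) - 1
  }
  if (2 %in% estimators) {
    out$f_snp2 <- 1 - unname(rowMeans(Y * (2 - Y) / H, na.rm = TRUE))
  }
  if (3 %in% estimators) {
    out$f_snp3 <- unname(rowMeans((Y^2 - Y * (1 + 2 * P) + 2 * P^2) / H,
                                  na.rm = TRUE))
  }
  out[n_used == 0, setdiff(names(out), "sample")] <- NA_real_
  out$n_snps_used <- n_used
  out
}

#' Assemble the per-sample inbreeding table
#'
#' Joins whichever coefficient sets are available — pedigree F_PED, the four
#' ROH-based coefficients, and the three SNP-by-SNP estimators — into one
#' table, one row per sample.
#'
#' @param ds A [geno_ds], for the SNP estimators (optional).
#' @param roh A `roh_set`, for F_ROH (optional).
#' @param ped A `pedigree`, for F_PED (optional).
#' @param l_auto_bp Autosome length override for F_ROH.
#' @return Tibble with `sample` plus the available coefficient columns.
#' @export
inbreeding_table <- function(ds = NULL, roh = NULL, ped = NULL,
                             l_auto_bp = NULL) {
  if (is.null(ds) && is.null(roh) && is.null(ped)) {
    abort("provide at least one of ds, roh, ped")
  }
  samples <- if (!is.null(ds)) ds$samples
             else if (!is.null(roh)) attr(roh, "samples")
             else ped$id
  out <- tibble::tibble(sample = samples)
  if (!is.null(ped)) {
    out <- dplyr::left_join(out, f_ped(ped, intersect(samples, ped$id)),
                            by = "sample")
  }
  if (!is.null(roh)) {
    out <- dplyr::left_join(out, f_roh(roh, l_auto_bp = l_auto_bp),
                            by = "sample")
  }
  if (!is.null(ds)) {
    out <- dplyr::left_join(out, dplyr::select(f_snp(ds), -"n_snps_used"),
                            by = "sample")
  }
  out
}

#' Pearson correlations among inbreeding coefficients
#'
#' Pairwise Pearson correlations over samples with complete values for each
#' pair of coefficient columns, for comparing the eight estimators.
#'
#' @param table An [inbreeding_table()] (column `sample` plus coefficients).
#' @return A symmetric correlation matrix with unit diagonal, of class
#'   `inbreeding_cor`.
#' @export
inbreeding_correlations <- function(table) {
  m <- as.matrix(dplyr::select(table, -dplyr::any_of("sample")))
  keep <- apply(m, 2, function(x) stats::var(x, na.rm = TRUE) > 0 || all(is.na(x)))
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  diag(r) <- 1
  structure(r, class = c("inbreeding_cor", "matrix"), kept = keep)
}
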