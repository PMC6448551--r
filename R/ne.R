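#' Map physical distance to recombination fraction
#'
#' Converts a physical distance to genetic distance at `cm_per_mb`
#' (`d_M = d_bp * cm_per_mb / 1e8` Morgan), then to a recombination fraction
#' via the chosen mapping function: Haldane `c = (1 - exp(-2 d)) / 2`
#' (no interference), Sved & Feldman `c = d / (1 + 2 d)`, or linear
#' `c = min(d, 0.5)`.
#'
#' @param d_bp Physical distance(s) in bp.
#' @param cm_per_mb Genetic map density (cM per Mb).
#' @param mapping One of "haldane", "sved", "linear".
#' @return Recombination fraction(s) in `[0, 0.5]`.
#' @export
physical_to_c <- function(d_bp, cm_per_mb = 1,
                          mapping = c("haldane", "sved", "linear")) {
  mapping <- match.arg(mapping)
  d <- d_bp * cm_per_mb / 1e8
  switch(mapping,
         haldane = 0.5 * (1 - exp(-2 * d)),
         sved = d / (1 + 2 * d),
         linear = pmin(d, 0.5))
}

#' Expected adjusted r-squared under drift-recombination equilibrium
#'
#' Sved's expectation `E[r2adj] = 1 / (alpha + 4 Ne c)` linking adjusted LD
#' to effective population size at recombination fraction `c`; `alpha` is 1
#' for drift only, 2 or 2.2 with a mutation correction. The inverse of
#' [ne_trajectory()]'s per-bin estimator, exposed for round-trip validation.
#'
#' @param ne Effective population size.
#' @param c_t Recombination fraction(s).
#' @param alpha Mutation-correction constant.
#' @return Expected adjusted r².
#' @export
sved_expected_r2 <- function(ne, c_t, alpha = 1) {
  1 / (alpha + 4 * ne * c_t)
}

#' Historical effective population size from binned LD decay
#'
#' Per distance bin with recombination fraction `c`, inverts Sved's
#' expectation: `Ne = (1 / mean_r2adj - alpha) / (4 c)`, dated at
#' `t = 1 / (2 c)` generations ago — longer distances (larger `c`) reflect
#' more recent effective size. Bins with fewer than `min_pairs` pairs are
#' dropped; bins whose adjusted LD is non-positive or at/below the `1/alpha`
#' boundary yield no estimate and are flagged.
#'
#' @param bins An [bin_ld()] table (or any tibble with `c_t`, `mean_r2adj`,
#'   `n_pairs`).
#' @param alpha Mutation-correction constant: 1 (drift only, default), 2, or
#'   2.2.
#' @param min_pairs Minimum pair count per usable bin (default 50).
#' @return Tibble of class `ne_trajectory`: t, ne, c_t, mean_r2adj, n_pairs,
#'   flag; sorted by t ascending.
#' @export
ne_trajectory <- function(bins, alpha = 1, min_pairs = 50) {
  stopifnot(alpha > 0)
  use <- bins$n_pairs >= min_pairs & !is.na(bins$mean_r2adj)
  if (!any(use)) abort("no usable LD bins (all below min_pairs or empty)")
  b <- bins[use, , drop = FALSE]
  ne <- (1 / b$mean_r2adj - alpha) / (4 * b$c_t)
  flag <- dplyr::case_when(
    b$mean_r2adj <= 0 ~ "nonpositive_r2adj",
    ne <= 0 ~ "boundary",
    .default = "ok")
  ne[flag != "ok"] <- NA_real_
  out <- tibble::tibble(t = 1 / (2 * b$c_t), ne = ne, c_t = b$c_t,
                        mean_r2adj = b$mean_r2adj, n_pairs = b$n_pairs,
                        flag = flag) |>
    dplyr::arrange(.data$t)
  class(out) <- c("ne_trajectory", class(out))
  out
}
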