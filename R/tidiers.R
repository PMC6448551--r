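#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and summarize a ROH segment set
#'
#' `tidy()` returns the plain segment table (one row per segment, lengths in
#' kb alongside bp); `glance()` returns one row per sample with segment count,
#' summed length, and the sample's overall F_ROH.
#'
#' @param x A `roh_set`.
#' @param ... Unused.
#' @export
tidy.roh_set <- function(x, ...) {
  tibble::tibble(sample = x$sample, chrom = x$chrom, start_bp = x$start_bp,
                 end_bp = x$end_bp, n_snps = x$n_snps,
                 length_kb = x$length_bp / 1e3, length_class = x$length_class)
}

#' @rdname tidy.roh_set
#' @export
glance.roh_set <- function(x, ...) {
  samples <- attr(x, "samples")
  l_auto <- attr(x, "l_auto_bp")
  tibble::tibble(sample = samples) |>
    dplyr::left_join(
      tibble::as_tibble(x) |>
        dplyr::group_by(.data$sample) |>
        dplyr::summarise(n_roh = dplyr::n(),
                         total_length_bp = sum(.data$length_bp),
                         .groups = "drop"),
      by = "sample") |>
    dplyr::mutate(n_roh = dplyr::coalesce(.data$n_roh, 0L),
                  total_length_bp = dplyr::coalesce(.data$total_length_bp, 0),
                  f_roh = .data$total_length_bp / l_auto)
}

#' @export
tidy.inbreeding_cor <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(as.data.frame(m), rownames = "coefficient") |>
    tidyr::pivot_longer(-"coefficient", names_to = "other",
                        values_to = "r")
}

#' @export
glance.ne_trajectory <- function(x, ...) {
  ok <- x$flag == "ok"
  tibble::tibble(n_bins = nrow(x), n_defined = sum(ok),
                 ne_recent = x$ne[ok][which.min(x$t[ok])],
                 ne_oldest = x$ne[ok][which.max(x$t[ok])])
}
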