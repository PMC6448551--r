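#' @importFrom rlang %||% abort warn .data
#' @importFrom stats cor pnorm qnorm rbinom rpois runif sd var complete.cases quantile
#' @importFrom utils head tail
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Sliding-window sums of a numeric/logical vector, window w, one-step stride.
# Returns length(x) - w + 1 values. Used by the fast ROH caller.
roll_sum <- function(x, w) {
  cs <- cumsum(c(0, as.numeric(x)))
  cs[(w + 1L):length(cs)] - cs[1:(length(cs) - w)]
}

# chrom-wise order check; returns TRUE or the offending (chrom, pos)
check_sorted_map <- function(map) {
  bad <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(c(FALSE, diff(.data$pos_bp) <= 0)) |>
    dplyr::ungroup()
  if (nrow(bad) > 0) {
    abort(sprintf(
      "variant positions not strictly increasing within chromosome: first offender %s:%s",
      bad$chrom[1], format(bad$pos_bp[1], scientific = FALSE)
    ))
  }
  invisible(TRUE)
}
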