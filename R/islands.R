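#' Per-SNP ROH incidence across individuals
#'
#' For every mapped SNP, counts the individuals carrying at least one ROH
#' segment spanning its position (segments of one individual never overlap,
#' so each individual contributes at most once).
#'
#' @param roh A `roh_set` from [call_roh()].
#' @param map Variant map of the dataset the ROH were called on.
#' @param n_samples Number of individuals; defaults to the value recorded on
#'   the `roh_set`.
#' @return A tibble of class `roh_incidence`: chrom, pos_bp, id, count,
#'   proportion.
#' @export
snp_roh_incidence <- function(roh, map, n_samples = NULL) {
  n_samples <- n_samples %||% length(attr(roh, "samples"))
  map <- tibble::as_tibble(map)
  count <- integer(nrow(map))
  for (chrom in unique(map$chrom)) {
    idx <- which(map$chrom == chrom)
    pos <- map$pos_bp[idx]
    segs <- roh[roh$chrom == chrom, , drop = FALSE]
    if (!nrow(segs)) next
    # difference-array accumulation over SNP index space
    d <- integer(length(idx) + 1L)
    a <- findInterval(segs$start_bp - 1, pos) + 1L   # first SNP >= start
    b <- findInterval(segs$end_bp, pos)              # last SNP <= end
    ok <- a <= b
    for (r in which(ok)) {
      d[a[r]] <- d[a[r]] + 1L
      d[b[r] + 1L] <- d[b[r] + 1L] - 1L
    }
    count[idx] <- cumsum(head(d, -1L))
  }
  out <- tibble::tibble(chrom = map$chrom, pos_bp = map$pos_bp, id = map$id,
                        count = count, proportion = count / n_samples)
  attr(out, "n_samples") <- n_samples
  class(out) <- c("roh_incidence", class(out))
  out
}

#' Detect ROH islands
#'
#' Island SNPs are the top `top_fraction` of SNPs by ROH incidence: the
#' threshold is the `ceiling(top_fraction * m)`-th largest incidence
#' proportion, and every SNP at or above it (ties included) is an island SNP,
#' so at least `ceiling(top_fraction * m)` SNPs are kept. Maximal runs of
#' consecutive island SNPs — strict adjacency in the map, no bridging across
#' a sub-threshold SNP — merge into island regions whose boundaries are SNP
#' positions.
#'
#' @param track A [snp_roh_incidence()] track.
#' @param top_fraction Fraction of SNPs to keep (default 0.005, i.e. top 0.5%).
#' @return Tibble of island regions: chrom, start_bp, end_bp, length_bp,
#'   n_snps, mean_abs_ihs (NA until [island_ihs_summary()]), with attributes
#'   `threshold` (realized proportion cutoff) and `n_island_snps`.
#' @export
detect_islands <- function(track, top_fraction = 0.005) {
  if (nrow(track) == 0L) abort("empty incidence track")
  prop <- track$proportion
  if (length(unique(prop)) == 1L) {
    abort("degenerate incidence: every SNP has the same ROH proportion")
  }
  m <- length(prop)
  rank <- m - ceiling(top_fraction * m) + 1L
  threshold <- sort(prop)[rank]
  is_island <- prop >= threshold
  out <- purrr::map_dfr(unique(track$chrom), function(chrom) {
    on <- track$chrom == chrom
    flag <- is_island[on]
    pos <- track$pos_bp[on]
    if (!any(flag)) return(NULL)
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    tibble::tibble(chrom = chrom,
                   start_bp = pos[starts[keep]], end_bp = pos[ends[keep]],
                   n_snps = r$lengths[keep])
  })
  out <- dplyr::mutate(out, length_bp = .data$end_bp - .data$start_bp + 1,
                       mean_abs_ihs = NA_real_, .after = "end_bp")
  attr(out, "threshold") <- threshold
  attr(out, "n_island_snps") <- sum(is_island)
  out
}

#' Detect ROH cold-spots
#'
#' Maximal runs of SNPs never covered by a ROH in any individual
#' (incidence count 0), reported with their SNP count and physical span,
#' sorted by span descending.
#'
#' @param track A [snp_roh_incidence()] track.
#' @return Tibble: chrom, start_bp, end_bp, n_snps, span_bp.
#' @export
detect_coldspots <- function(track) {
  out <- purrr::map_dfr(unique(track$chrom), function(chrom) {
    on <- track$chrom == chrom
    zero <- track$count[on] == 0L
    pos <- track$pos_bp[on]
    if (!any(zero)) return(NULL)
    r <- rle(zero)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    tibble::tibble(chrom = chrom,
                   start_bp = pos[starts[keep]], end_bp = pos[ends[keep]],
                   n_snps = r$lengths[keep])
  })
  if (nrow(out) == 0L) {
    return(tibble::tibble(chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), n_snps = integer(),
                          span_bp = numeric()))
  }
  out |>
    dplyr::mutate(span_bp = .data$end_bp - .data$start_bp + 1) |>
    dplyr::arrange(dplyr::desc(.data$span_bp))
}
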