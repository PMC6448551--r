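#' Build a genotype dataset
#'
#' The central container of the package: an ordered set of diploid samples, a
#' physical variant map, and a samples-by-variants matrix of counted-allele
#' copies (0, 1, 2, or `NA` for missing). All downstream stages — QC, ROH
#' calling, inbreeding estimation, LD, island detection — consume this object.
#'
#' @param samples Character vector of sample ids (unique).
#' @param map A data frame with columns `chrom`, `pos_bp` (1-based physical
#'   position), `id`, `ref`, `alt`, and optionally `anc` (ancestral allele,
#'   used by the iHS scan). Positions must be strictly increasing within each
#'   chromosome; every marker is biallelic.
#' @param calls Integer matrix, `length(samples)` rows by `nrow(map)` columns,
#'   values in `{0, 1, 2, NA}` counting copies of the `alt` allele.
#' @param l_auto_bp Total mapped autosome length in bp, the denominator of
#'   ROH-based inbreeding (F_ROH = L_ROH / L_auto). Defaults to the summed
#'   per-chromosome span `max(pos) - min(pos) + 1`; override it when the map
#'   covers a known larger assembly (e.g. 2.26e9 for a 2.26 Gb genome).
#' @param haps Optional phased haplotypes: a `2 * length(samples)` by
#'   `nrow(map)` binary matrix, rows `2i - 1` and `2i` being the two
#'   haplotypes of sample `i`. Required by the EHH/iHS machinery.
#'
#' @return An object of class `geno_ds`.
#' @export
geno_ds <- function(samples, map, calls, l_auto_bp = NULL, haps = NULL) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) abort("duplicated sample ids")
  map <- tibble::as_tibble(map)
  need <- c("chrom", "pos_bp", "id", "ref", "alt")
  if (!all(need %in% names(map))) {
    abort(paste("map must have columns", paste(need, collapse = ", ")))
  }
  if (!"anc" %in% names(map)) map$anc <- NA_character_
  map$chrom <- as.character(map$chrom)
  check_sorted_map(map)
  if (any(!is.na(map$ref) & !is.na(map$alt) & map$ref == map$alt)) {
    abort("ref and alt allele identical at some marker: markers must be biallelic")
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(map)) {
    abort(sprintf(
      "calls must be %d samples x %d variants, got %d x %d",
      length(samples), nrow(map), nrow(calls), ncol(calls)
    ))
  }
  vals <- calls[!is.na(calls)]
  if (length(vals) && !all(vals %in% 0:2)) abort("calls must be 0, 1, 2 or NA")
  rownames(calls) <- samples
  colnames(calls) <- map$id
  if (!is.null(haps)) {
    haps <- as.matrix(haps)
    storage.mode(haps) <- "integer"
    if (nrow(haps) != 2L * length(samples) || ncol(haps) != nrow(map)) {
      abort("haps must be 2*n_samples x n_variants")
    }
    if (length(haps) && !all(haps %in% 0:1)) abort("haplotype alleles must be 0/1")
  }
  span <- sum(tapply(map$pos_bp, map$chrom, function(p) max(p) - min(p) + 1))
  if (nrow(map) == 0L) span <- 0
  l_auto_bp <- l_auto_bp %||% span
  if (l_auto_bp < span) abort("l_auto_bp smaller than the span of the variant map")
  structure(
    list(samples = samples, map = map, calls = calls,
         l_auto_bp = as.numeric(l_auto_bp), haps = haps),
    class = "geno_ds"
  )
}

#' @export
print.geno_ds <- function(x, ...) {
  cat(sprintf(
    "<geno_ds> %d samples x %d variants on %d chromosome(s); L_auto = %s bp%s\n",
    length(x$samples), nrow(x$map), length(unique(x$map$chrom)),
    format(x$l_auto_bp, big.mark = ",", scientific = FALSE),
    if (is.null(x$haps)) "" else "; phased"
  ))
  invisible(x)
}

#' @export
dim.geno_ds <- function(x) c(length(x$samples), nrow(x$map))

n_samples <- function(ds) length(ds$samples)
n_variants <- function(ds) nrow(ds$map)

# subset variants by logical/integer index, keeping samples
subset_variants <- function(ds, keep) {
  geno_ds(ds$samples, ds$map[keep, , drop = FALSE],
          ds$calls[, keep, drop = FALSE], l_auto_bp = ds$l_auto_bp,
          haps = if (is.null(ds$haps)) NULL else ds$haps[, keep, drop = FALSE])
}

#' Per-variant alternate-allele frequency
#'
#' Frequency of the counted (alt) allele from non-missing calls.
#'
#' @param ds A [geno_ds].
#' @return Numeric vector, `NaN` for all-missing variants.
#' @export
allele_freq <- function(ds) {
  unname(colMeans(ds$calls, na.rm = TRUE)) / 2
}
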