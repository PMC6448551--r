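#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (via vcfR) into a [geno_ds]. Calls are coded as
#' ALT-allele counts; missing genotypes become `NA`. If every genotype in the
#' file is phased (`|` separator), the haplotypes are retained and the iHS
#' machinery can run on the result.
#'
#' @param path Path to an uncompressed or bgzipped VCF with a GT field.
#' @param skip_multiallelic Drop records with more than one ALT allele instead
#'   of erroring.
#' @param l_auto_bp Optional override for the autosome length (see [geno_ds]).
#' @return A [geno_ds].
#' @export
read_vcf <- function(path, skip_multiallelic = FALSE, l_auto_bp = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(v)
  if (is.null(dim(fix_mat))) {
    fix_mat <- matrix(fix_mat, nrow = 1, dimnames = list(NULL, names(fix_mat)))
  }
  fix <- tibble::as_tibble(as.data.frame(fix_mat, stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) {
    samples <- colnames(v@gt)[-1] %||% character()
    return(geno_ds(samples,
                   tibble::tibble(chrom = character(), pos_bp = integer(),
                                  id = character(), ref = character(), alt = character()),
                   matrix(integer(), nrow = length(samples), ncol = 0),
                   l_auto_bp = l_auto_bp))
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi) && !skip_multiallelic) {
    abort(sprintf("multiallelic record at %s:%s (set skip_multiallelic = TRUE to drop)",
                  fix$CHROM[multi][1], fix$POS[multi][1]))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  map <- tibble::tibble(
    chrom = fix$CHROM,
    pos_bp = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID),
    ref = fix$REF, alt = fix$ALT
  )
  # order check before building the object so the error names the file's culprit
  check_sorted_map(map)
  samples <- colnames(gt)
  norm <- gsub("|", "/", gt, fixed = TRUE)
  miss <- is.na(norm) | grepl(".", norm, fixed = TRUE)
  cnt <- nchar(norm) - nchar(gsub("1", "", norm, fixed = TRUE))
  cnt[miss] <- NA_integer_
  calls <- t(matrix(as.integer(cnt), nrow = nrow(gt), ncol = length(samples)))
  haps <- NULL
  phased <- !is.na(gt) & grepl("|", gt, fixed = TRUE) & !grepl(".", gt, fixed = TRUE)
  unphased_present <- any(!is.na(gt) & !grepl("|", gt, fixed = TRUE))
  if (nrow(gt) > 0 && all(phased | is.na(gt)) && !unphased_present && !anyNA(gt)) {
    a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
    haps <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(gt))
    for (s in seq_along(samples)) {
      haps[2L * s - 1L, ] <- as.integer(a1[, s])
      haps[2L * s, ] <- as.integer(a2[, s])
    }
  }
  geno_ds(samples, map, calls, l_auto_bp = l_auto_bp, haps = haps)
}

#' Write a genotype dataset as plain-text VCF
#'
#' Emits an uncompressed VCF 4.2 with GT-only genotypes. Phased haplotypes,
#' when present on the dataset, are written with the `|` separator so a
#' round-trip through [read_vcf()] preserves them.
#'
#' @param ds A [geno_ds].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ds$samples), collapse = "\t")), con)
  m <- n_variants(ds)
  if (m == 0L) return(invisible(path))
  if (!is.null(ds$haps)) {
    i1 <- seq(1L, 2L * n_samples(ds), by = 2L)
    gt <- matrix(paste0(ds$haps[i1, , drop = FALSE], "|",
                        ds$haps[i1 + 1L, , drop = FALSE]),
                 nrow = n_samples(ds))
  } else {
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = n_samples(ds), ncol = m)
    ok <- !is.na(ds$calls)
    gt[ok] <- code[ds$calls[ok] + 1L]
  }
  body <- vapply(seq_len(m), function(j) {
    paste(c(ds$map$chrom[j], ds$map$pos_bp[j], ds$map$id[j], ds$map$ref[j],
            ds$map$alt[j], ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from PLINK text PED/MAP files
#'
#' @param ped_path Path to a whitespace-delimited PED file: six leading columns
#'   (FID, IID, PAT, MAT, SEX, PHENO) then two allele columns per marker;
#'   missing alleles coded `0`.
#' @param map_path Path to the matching MAP file (chrom, id, cM, bp).
#' @param counted_alleles Optional character vector (one per marker) naming the
#'   allele to count as 2. By default the counted allele is the second allele
#'   observed when scanning genotypes in sample order (the "first-listed
#'   alternate"); pass the known ALT alleles for exact cross-format agreement
#'   with [read_vcf()].
#' @param l_auto_bp Optional autosome-length override.
#' @return A [geno_ds].
#' @export
read_plink_text <- function(ped_path, map_path, counted_alleles = NULL,
                            l_auto_bp = NULL) {
  mp <- readr::read_table(map_path,
                          col_names = c("chrom", "id", "cm", "pos_bp"),
                          col_types = "ccdi", progress = FALSE)
  ped <- readr::read_table(ped_path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  m <- nrow(mp)
  if (ncol(ped) != 6L + 2L * m) {
    abort(sprintf("PED has %d allele columns but MAP lists %d markers",
                  ncol(ped) - 6L, m))
  }
  samples <- ped[[2]]
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  calls <- matrix(NA_integer_, nrow = length(samples), ncol = m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    obs <- c(rbind(a1[, j], a2[, j]))
    lev <- unique(obs[!is.na(obs)])
    if (length(lev) > 2L) {
      abort(sprintf("marker %s has %d alleles; only biallelic markers supported",
                    mp$id[j], length(lev)))
    }
    if (length(lev) == 0L) lev <- c("N", "N2")
    if (length(lev) == 1L) lev <- c(lev, NA)
    counted <- counted_alleles[j] %||% lev[2]
    other <- setdiff(lev, counted)[1]
    ref[j] <- ifelse(is.na(other), "N", other)
    alt[j] <- ifelse(is.na(counted), paste0(ref[j], "x"), counted)
    calls[, j] <- (!is.na(a1[, j]) & a1[, j] == counted) +
      (!is.na(a2[, j]) & a2[, j] == counted)
    calls[is.na(a1[, j]) | is.na(a2[, j]), j] <- NA_integer_
  }
  map <- tibble::tibble(chrom = mp$chrom, pos_bp = mp$pos_bp, id = mp$id,
                        ref = ref, alt = alt)
  geno_ds(samples, map, calls, l_auto_bp = l_auto_bp)
}

#' Write a genotype dataset as PLINK text PED/MAP
#'
#' @param ds A [geno_ds].
#' @param prefix Output prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The two paths, invisibly.
#' @export
write_plink_text <- function(ds, prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  readr::write_tsv(
    tibble::tibble(chrom = ds$map$chrom, id = ds$map$id, cm = 0,
                   pos_bp = ds$map$pos_bp),
    map_path, col_names = FALSE, progress = FALSE)
  m <- n_variants(ds)
  lines <- vapply(seq_len(n_samples(ds)), function(i) {
    g <- ds$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, ds$map$alt, ds$map$ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, ds$map$alt, ds$map$ref))
    paste(c("FAM", ds$samples[i], "0", "0", "0", "-9", rbind(a1, a2)),
          collapse = " ")
  }, character(1))
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a pedigree table
#'
#' Reads a delimited file (comma, tab, or whitespace) whose first three columns
#' are individual id, sire id, and dam id; unknown parents coded `0` or empty.
#' The result is topologically sorted (parents before offspring). Parents that
#' appear only in the sire/dam columns are appended as founder records with a
#' warning. A cyclic pedigree is an error.
#'
#' @param path Path to the pedigree file. A header row is detected when the
#'   first field is non-numeric and matches `id` (case-insensitive).
#' @return A tibble of class `pedigree` with columns `id`, `sire`, `dam`
#'   (`NA` = unknown), in topological order.
#' @export
read_pedigree <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  delim <- if (any(grepl(",", raw))) "," else "[\t ]+"
  parts <- strsplit(raw, delim)
  parts <- lapply(parts, function(x) trimws(x[nzchar(trimws(x))]))
  if (length(parts) && tolower(parts[[1]][1]) %in% c("id", "iid", "animal")) {
    parts <- parts[-1]
  }
  if (any(lengths(parts) < 3L)) abort("pedigree rows need at least 3 columns (id, sire, dam)")
  tab <- tibble::tibble(
    id = vapply(parts, `[`, "", 1),
    sire = vapply(parts, `[`, "", 2),
    dam = vapply(parts, `[`, "", 3)
  )
  as_pedigree(tab)
}

#' Coerce a data frame to a pedigree
#'
#' @param x Data frame with columns `id`, `sire`, `dam`; unknown parents `0`,
#'   empty, or `NA`.
#' @return A topologically sorted `pedigree` tibble.
#' @export
as_pedigree <- function(x) {
  tab <- tibble::tibble(id = as.character(x$id), sire = as.character(x$sire),
                        dam = as.character(x$dam))
  tab$sire[tab$sire %in% c("0", "") | is.na(tab$sire)] <- NA
  tab$dam[tab$dam %in% c("0", "") | is.na(tab$dam)] <- NA
  if (anyDuplicated(tab$id)) abort("duplicated individual ids in pedigree")
  parents <- setdiff(stats::na.omit(c(tab$sire, tab$dam)), tab$id)
  if (length(parents)) {
    warn(sprintf("%d parent(s) without own record added as founders: %s",
                 length(parents), paste(head(parents, 5), collapse = ", ")))
    tab <- dplyr::bind_rows(
      tibble::tibble(id = parents, sire = NA_character_, dam = NA_character_), tab)
  }
  # Kahn topological sort; leftovers form a cycle
  ord <- character(0)
  placed <- character(0)
  remaining <- tab
  repeat {
    ready <- (is.na(remaining$sire) | remaining$sire %in% placed) &
      (is.na(remaining$dam) | remaining$dam %in% placed)
    if (!any(ready)) break
    ord <- c(ord, remaining$id[ready])
    placed <- ord
    remaining <- remaining[!ready, , drop = FALSE]
    if (nrow(remaining) == 0L) break
  }
  if (nrow(remaining) > 0L) {
    abort(sprintf("pedigree contains a cycle involving: %s",
                  paste(remaining$id, collapse = ", ")))
  }
  out <- tab[match(ord, tab$id), ]
  class(out) <- c("pedigree", class(out))
  out
}

#' Write genomic intervals as BED3
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based half-open,
#' i.e. `(start_bp - 1, end_bp)`.
#'
#' @param intervals Data frame with columns `chrom`, `start_bp`, `end_bp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(intervals)))
  if (any(intervals$start_bp > intervals$end_bp)) abort("interval with start_bp > end_bp")
  readr::write_tsv(
    tibble::tibble(chrom = intervals$chrom,
                   start = intervals$start_bp - 1L,
                   end = intervals$end_bp),
    path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED3 file into 1-based inclusive intervals
#'
#' @param path Path to a BED3 file.
#' @return Tibble with `chrom`, `start_bp`, `end_bp` (1-based inclusive).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(chrom = character(), start_bp = integer(),
                          end_bp = integer()))
  }
  b <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                       col_types = "cii", progress = FALSE)
  tibble::tibble(chrom = b$chrom, start_bp = b$start + 1L, end_bp = b$end)
}
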