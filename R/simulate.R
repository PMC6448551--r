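#' Build a regular synthetic variant map
#'
#' Evenly spaced biallelic markers on one or more autosomes. The default
#' spacing (one marker per 13.6 kb) matches the density of a
#' reduced-representation sequencing panel on a livestock genome.
#'
#' @param n_chrom Number of autosomes.
#' @param chrom_length_bp Length of each autosome in bp.
#' @param spacing_bp Inter-marker spacing in bp.
#' @return A variant map tibble usable by [geno_ds()]; the reference allele is
#'   also recorded as ancestral (`anc`), matching the simulator's convention
#'   that allele 0 is ancestral.
#' @export
sim_map <- function(n_chrom = 3, chrom_length_bp = 5e7, spacing_bp = 13600) {
  purrr::map_dfr(seq_len(n_chrom), function(cc) {
    pos <- seq(spacing_bp, chrom_length_bp, by = spacing_bp)
    tibble::tibble(chrom = as.character(cc), pos_bp = as.integer(pos),
                   id = sprintf("c%d_%d", cc, pos),
                   ref = "A", alt = "G", anc = "A")
  })
}

#' Sample a pool of founder haplotypes
#'
#' Generates `2 * n_founders` binary haplotypes over a variant map. Per-marker
#' allele frequencies are drawn uniformly from `maf_range`; linkage
#' disequilibrium decaying with distance is induced by a first-order Markov
#' copying process along each chromosome: at each successive marker the
#' haplotype keeps its previous allele with probability `rho`, otherwise draws
#' a fresh allele at that marker's frequency. This is a deliberately simple LD
#' model (not a coalescent): adjacent-marker correlation is about `rho`,
#' decaying geometrically with marker separation.
#'
#' @param n_founders Number of founder individuals (>= 2).
#' @param map Variant map (see [sim_map()]).
#' @param maf_range Interval in (0, 0.5] for per-marker allele frequencies.
#' @param rho Copying probability in `[0, 1)`; 0 gives linkage equilibrium.
#' @param seed Integer seed; the pool is bit-reproducible given the seed.
#' @return A `founder_pool`: list with `haplotypes` (2F x M binary matrix),
#'   `map`, `freq` (the drawn target frequencies), and `rho`.
#' @export
sample_founders <- function(n_founders, map, maf_range = c(0.05, 0.5),
                            rho = 0.9, seed = NULL) {
  if (n_founders < 2) abort("need at least 2 founders")
  stopifnot(rho >= 0, rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2])
  map <- tibble::as_tibble(map)
  check_sorted_map(map)
  m <- nrow(map)
  nh <- 2L * n_founders
  with_seed(seed, {
    p <- runif(m, maf_range[1], maf_range[2])
    H <- matrix(0L, nrow = nh, ncol = m)
    new_chrom <- c(TRUE, map$chrom[-1] != map$chrom[-m])
    for (j in seq_len(m)) {
      fresh <- rbinom(nh, 1L, p[j])
      if (new_chrom[j]) {
        H[, j] <- fresh
      } else {
        keep <- runif(nh) < rho
        H[, j] <- ifelse(keep, H[, j - 1L], fresh)
      }
    }
    structure(list(haplotypes = H, map = map, freq = p, rho = rho),
              class = "founder_pool")
  })
}

#' @export
print.founder_pool <- function(x, ...) {
  cat(sprintf("<founder_pool> %d haplotypes x %d markers (rho = %g)\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$rho))
  invisible(x)
}

#' Assemble an unrelated diploid population from a founder pool
#'
#' Each individual receives two distinct pool haplotypes (drawn without
#' replacement across the population when the pool is large enough), so
#' individuals carry no identical-by-descent tracts by construction.
#'
#' @param pool A `founder_pool`.
#' @param n_ind Number of individuals.
#' @param seed Integer seed.
#' @param l_auto_bp Optional autosome-length override passed to [geno_ds()].
#' @return A phased [geno_ds].
#' @export
assemble_population <- function(pool, n_ind, seed = NULL, l_auto_bp = NULL) {
  nh <- nrow(pool$haplotypes)
  with_seed(seed, {
    if (2L * n_ind <= nh) {
      idx <- sample.int(nh, 2L * n_ind)
    } else {
      idx <- unlist(lapply(seq_len(n_ind), function(i) sample.int(nh, 2L)))
    }
    haps <- pool$haplotypes[idx, , drop = FALSE]
    i1 <- seq(1L, 2L * n_ind, by = 2L)
    calls <- haps[i1, , drop = FALSE] + haps[i1 + 1L, , drop = FALSE]
    geno_ds(sprintf("ind%03d", seq_len(n_ind)), pool$map, calls,
            l_auto_bp = l_auto_bp, haps = haps)
  })
}

empty_truth <- function() {
  tibble::tibble(sample = character(), chrom = character(),
                 start_bp = numeric(), end_bp = numeric(), hap = integer())
}

# ---- gene dropping ---------------------------------------------------------

# A gamete on one chromosome: integer-ish breakpoints as parallel vectors
# `end` (increasing, last = chrom_max) and `hap` (founder haplotype id).
# Starts are implicit: chrom_min, end[1]+1, ...

# clip a gamete to [a, b]
gamete_clip <- function(gam, a, b) {
  i <- which(gam$end >= a)
  j <- which(gam$end >= b)[1]
  keep <- i[i <= j]
  list(end = c(head(gam$end[keep], -1), b), hap = gam$hap[keep])
}

gamete_merge <- function(end, hap) {
  if (length(hap) <= 1L) return(list(end = end, hap = hap))
  same <- c(hap[-1] == hap[-length(hap)], FALSE)
  list(end = end[!same], hap = hap[!same])
}

# recombine one chromosome of a parent's two gametes into a child gamete
meiosis_chrom <- function(g1, g2, cmin, cmax, morgans) {
  nxo <- rpois(1L, morgans)
  if (nxo > 0) {
    xo <- sort(floor(runif(nxo, cmin, cmax)))
    xo <- unique(pmin(pmax(xo, cmin), cmax - 1))
  } else xo <- numeric(0)
  bounds <- c(xo, cmax)
  starts <- c(cmin, xo + 1)
  src <- ((seq_along(bounds) - 1L + sample.int(2L, 1L) - 1L) %% 2L) + 1L
  ends <- numeric(0); haps <- integer(0)
  for (k in seq_along(bounds)) {
    g <- if (src[k] == 1L) g1 else g2
    piece <- gamete_clip(g, starts[k], bounds[k])
    ends <- c(ends, piece$end); haps <- c(haps, piece$hap)
  }
  gamete_merge(ends, haps)
}

# overlap of two gametes: runs where both carry the same founder haplotype
ibd_tracts_chrom <- function(g1, g2, cmin) {
  cuts <- sort(unique(c(g1$end, g2$end)))
  starts <- c(cmin, head(cuts, -1) + 1)
  h1 <- g1$hap[findInterval(starts, c(cmin, head(g1$end, -1) + 1))]
  h2 <- g2$hap[findInterval(starts, c(cmin, head(g2$end, -1) + 1))]
  same <- h1 == h2
  if (!any(same)) return(NULL)
  r <- rle(same)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  ok <- r$values
  tibble::tibble(start_bp = starts[idx_start[ok]], end_bp = cuts[idx_end[ok]],
                 hap = h1[idx_start[ok]])
}

#' Gene-dropping simulation down a pedigree
#'
#' Drops founder haplotypes through a pedigree with recombination, tracking
#' the founder origin of every chromosome segment. Transmission follows the
#' Haldane model: crossover counts are Poisson with mean equal to the
#' chromosome's genetic length in Morgans (physical length times `cm_per_mb`),
#' crossover positions uniform, no interference. True autozygous (IBD) tracts
#' are the maximal runs where an individual's two gametes descend from the
#' same founder haplotype.
#'
#' @param ped A `pedigree` (see [read_pedigree()] / [as_pedigree()]).
#' @param pool A `founder_pool`; each founder (and each unknown-parent gamete)
#'   consumes pool haplotypes, which must suffice.
#' @param cm_per_mb Genetic map density, cM per Mb (default 1, i.e. 1 Mb = 1 cM).
#' @param seed Integer seed.
#' @return A list with `ds` (phased [geno_ds] over all pedigree members),
#'   `truth` (tibble of autozygous tracts: sample, chrom, start_bp, end_bp,
#'   hap), and `f_true` (tibble: sample, f_true = autozygous fraction of
#'   L_auto).
#' @export
gene_drop <- function(ped, pool, cm_per_mb = 1, seed = NULL) {
  if (nrow(ped) == 0L) abort("empty pedigree")
  map <- pool$map
  chroms <- unique(map$chrom)
  cinfo <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(cmin = min(.data$pos_bp), cmax = max(.data$pos_bp),
                     .groups = "drop")
  cinfo <- cinfo[match(chroms, cinfo$chrom), ]
  morgans <- (cinfo$cmax - cinfo$cmin + 1) * cm_per_mb / 1e8
  nh <- nrow(pool$haplotypes)
  with_seed(seed, {
    next_hap <- 0L
    fresh_gamete <- function() {
      next_hap <<- next_hap + 1L
      if (next_hap > nh) abort("founder pool exhausted: too many founder gametes for the pool")
      lapply(seq_along(chroms), function(k) list(end = cinfo$cmax[k], hap = next_hap))
    }
    gametes <- list()  # per individual: list(g1, g2), each a per-chrom list
    for (i in seq_len(nrow(ped))) {
      id <- ped$id[i]
      gam_from <- function(parent) {
        if (is.na(parent)) return(fresh_gamete())
        pg <- gametes[[parent]]
        lapply(seq_along(chroms), function(k) {
          meiosis_chrom(pg[[1]][[k]], pg[[2]][[k]],
                        cinfo$cmin[k], cinfo$cmax[k], morgans[k])
        })
      }
      gametes[[id]] <- list(gam_from(ped$sire[i]), gam_from(ped$dam[i]))
    }
    # truth tracts
    truth <- purrr::map_dfr(ped$id, function(id) {
      purrr::map_dfr(seq_along(chroms), function(k) {
        tr <- ibd_tracts_chrom(gametes[[id]][[1]][[k]], gametes[[id]][[2]][[k]],
                               cinfo$cmin[k])
        if (is.null(tr)) return(NULL)
        dplyr::mutate(tr, sample = id, chrom = chroms[k], .before = 1)
      })
    })
    if (nrow(truth) == 0L) truth <- empty_truth()
    # genotypes from founder haplotypes
    m <- nrow(map)
    n <- nrow(ped)
    haps <- matrix(0L, nrow = 2L * n, ncol = m)
    pos_by_chrom <- split(seq_len(m), map$chrom)[chroms]
    for (i in seq_len(n)) {
      for (gi in 1:2) {
        row <- 2L * (i - 1L) + gi
        for (k in seq_along(chroms)) {
          idx <- pos_by_chrom[[k]]
          pos <- map$pos_bp[idx]
          gam <- gametes[[ped$id[i]]][[gi]][[k]]
          seg_start <- c(cinfo$cmin[k], head(gam$end, -1) + 1)
          src <- gam$hap[findInterval(pos, seg_start)]
          haps[row, idx] <- pool$haplotypes[cbind(src, idx)]
        }
      }
    }
    i1 <- seq(1L, 2L * n, by = 2L)
    calls <- haps[i1, , drop = FALSE] + haps[i1 + 1L, , drop = FALSE]
    ds <- geno_ds(ped$id, map, calls, haps = haps)
    f_true <- tibble::tibble(sample = ped$id) |>
      dplyr::left_join(
        truth |>
          dplyr::group_by(.data$sample) |>
          dplyr::summarise(len = sum(.data$end_bp - .data$start_bp + 1),
                           .groups = "drop"),
        by = "sample") |>
      dplyr::mutate(f_true = dplyr::coalesce(.data$len, 0) / ds$l_auto_bp) |>
      dplyr::select("sample", "f_true")
    list(ds = ds, truth = truth, f_true = f_true)
  })
}

# ---- direct tract planting -------------------------------------------------

# draw one non-overlapping placement on the dataset's map; NULL if it fails
place_tract <- function(cinfo, occupied, len) {
  for (try in 1:200) {
    k <- sample.int(nrow(cinfo), 1L, prob = cinfo$span)
    lo <- cinfo$cmin[k]; hi <- cinfo$cmax[k] - len
    if (hi <= lo) next
    a <- floor(runif(1, lo, hi))
    b <- a + len - 1
    occ <- occupied[[k]]
    if (is.null(occ) || !any(a <= occ$end & b >= occ$start)) {
      return(list(k = k, start = a, end = b))
    }
  }
  NULL
}

#' Plant autozygous tracts with known truth
#'
#' A direct-control alternative to [gene_drop()] for calibration: per
#' individual, non-overlapping tracts are drawn (lengths exponential with the
#' given mean, or fixed) and placed uniformly until the autozygous fraction of
#' the genome reaches `fraction`. Within a tract the individual's second
#' haplotype is overwritten with its first, so every site inside is homozygous
#' and allele frequencies are approximately preserved.
#'
#' @param ds A phased [geno_ds] (see [assemble_population()]).
#' @param fraction Target autozygous genome fraction per individual, in `[0,1]`.
#' @param mean_length_mb Mean tract length in Mb (default 4.11, a realistic
#'   sequence-data ROH mean for an inbred livestock population).
#' @param length_dist `"exponential"` (default) or `"fixed"`.
#' @param seed Integer seed.
#' @return A list with `ds` (modified dataset), `truth`, and `f_true`, shaped
#'   as in [gene_drop()] (planted tracts carry `hap = NA`).
#' @export
plant_roh <- function(ds, fraction, mean_length_mb = 4.11,
                      length_dist = c("exponential", "fixed"), seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  length_dist <- match.arg(length_dist)
  if (is.null(ds$haps)) abort("plant_roh needs a phased dataset (haps present)")
  cinfo <- ds$map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(cmin = min(.data$pos_bp), cmax = max(.data$pos_bp),
                     .groups = "drop") |>
    dplyr::mutate(span = .data$cmax - .data$cmin + 1)
  target_bp <- fraction * ds$l_auto_bp
  mean_bp <- mean_length_mb * 1e6
  if (fraction > 0 && target_bp < 1e5) {
    warn("requested fraction smaller than the shortest placeable tract; nothing planted")
    target_bp <- 0
  }
  out <- ds
  with_seed(seed, {
    truth <- purrr::map_dfr(seq_along(ds$samples), function(i) {
      if (target_bp <= 0) return(NULL)
      if (fraction >= 1) {
        # full autozygosity: one tract per chromosome end to end
        return(tibble::tibble(sample = ds$samples[i], chrom = cinfo$chrom,
                              start_bp = cinfo$cmin, end_bp = cinfo$cmax,
                              hap = NA_integer_))
      }
      occupied <- vector("list", nrow(cinfo))
      placed <- list()
      tot <- 0
      while (tot < target_bp) {
        remaining <- target_bp - tot
        if (remaining < 1e5) break
        len <- if (length_dist == "fixed") mean_bp else stats::rexp(1, 1 / mean_bp)
        # cap the final tract at the remaining target so the realized
        # autozygous fraction lands on `fraction` (no inspection-paradox
        # overshoot); floor at 100 kb, the shortest placeable tract
        len <- max(round(min(len, remaining)), 1e5)
        pl <- place_tract(cinfo, occupied, len)
        if (is.null(pl)) break
        occupied[[pl$k]] <- dplyr::bind_rows(
          occupied[[pl$k]], tibble::tibble(start = pl$start, end = pl$end))
        placed <- c(placed, list(tibble::tibble(
          sample = ds$samples[i], chrom = cinfo$chrom[pl$k],
          start_bp = pl$start, end_bp = pl$end, hap = NA_integer_)))
        tot <- tot + len
      }
      dplyr::bind_rows(placed)
    })
    if (nrow(truth) == 0L) truth <- empty_truth()
    if (nrow(truth) > 0) {
      for (r in seq_len(nrow(truth))) {
        i <- match(truth$sample[r], ds$samples)
        on_chrom <- out$map$chrom == truth$chrom[r]
        idx <- which(on_chrom & out$map$pos_bp >= truth$start_bp[r] &
                       out$map$pos_bp <= truth$end_bp[r])
        if (!length(idx)) next
        out$haps[2L * i, idx] <- out$haps[2L * i - 1L, idx]
        out$calls[i, idx] <- 2L * out$haps[2L * i - 1L, idx]
      }
    }
    f_true <- tibble::tibble(sample = ds$samples) |>
      dplyr::left_join(
        truth |>
          dplyr::group_by(.data$sample) |>
          dplyr::summarise(len = sum(.data$end_bp - .data$start_bp + 1),
                           .groups = "drop"),
        by = "sample") |>
      dplyr::mutate(f_true = dplyr::coalesce(.data$len, 0) / ds$l_auto_bp) |>
      dplyr::select("sample", "f_true")
    list(ds = out, truth = truth, f_true = f_true)
  })
}

#' Plant one shared autozygous tract across many individuals
#'
#' Makes a fixed genomic window homozygous (second haplotype overwritten by
#' the first) in a random subset of individuals — the ground truth for ROH
#' island recovery tests.
#'
#' @param ds A phased [geno_ds].
#' @param chrom,start_bp,end_bp The window to make homozygous.
#' @param carrier_fraction Fraction of individuals receiving the tract.
#' @param seed Integer seed.
#' @return A list with `ds` and `truth` (one row per carrier).
#' @export
plant_shared_tract <- function(ds, chrom, start_bp, end_bp,
                               carrier_fraction, seed = NULL) {
  if (is.null(ds$haps)) abort("plant_shared_tract needs a phased dataset")
  with_seed(seed, {
    n <- n_samples(ds)
    carriers <- sort(sample.int(n, round(carrier_fraction * n)))
    idx <- which(ds$map$chrom == as.character(chrom) &
                   ds$map$pos_bp >= start_bp & ds$map$pos_bp <= end_bp)
    out <- ds
    for (i in carriers) {
      out$haps[2L * i, idx] <- out$haps[2L * i - 1L, idx]
      out$calls[i, idx] <- 2L * out$haps[2L * i - 1L, idx]
    }
    list(ds = out,
         truth = tibble::tibble(sample = ds$samples[carriers],
                                chrom = as.character(chrom),
                                start_bp = start_bp, end_bp = end_bp))
  })
}

#' Plant a selective sweep in a founder pool
#'
#' A fraction of pool haplotypes become carriers of the derived allele at the
#' focal marker and are overwritten with one shared core haplotype over
#' `focal position +/- core_half_len_bp` — an idealized hard sweep whose
#' extended haplotype homozygosity the iHS scan should detect.
#'
#' @param pool A `founder_pool`.
#' @param focal Focal marker index (column of the pool).
#' @param carrier_freq Derived-allele frequency in `(0, 1)`.
#' @param core_half_len_bp Half-length of the shared core haplotype in bp.
#' @param seed Integer seed.
#' @return A list with `pool` (modified) and `truth` (focal index, carrier
#'   frequency, half-length, carrier rows).
#' @export
plant_sweep <- function(pool, focal, carrier_freq, core_half_len_bp,
                        seed = NULL) {
  stopifnot(focal >= 1, focal <= ncol(pool$haplotypes),
            carrier_freq > 0, carrier_freq < 1)
  with_seed(seed, {
    nh <- nrow(pool$haplotypes)
    carriers <- sort(sample.int(nh, round(carrier_freq * nh)))
    map <- pool$map
    idx <- which(map$chrom == map$chrom[focal] &
                   map$pos_bp >= map$pos_bp[focal] - core_half_len_bp &
                   map$pos_bp <= map$pos_bp[focal] + core_half_len_bp)
    out <- pool
    if (length(idx) && length(carriers) > 1L) {
      template <- out$haplotypes[carriers[1], idx]
      out$haplotypes[carriers, idx] <- matrix(template, nrow = length(carriers),
                                              ncol = length(idx), byrow = TRUE)
    }
    out$haplotypes[, focal] <- 0L
    out$haplotypes[carriers, focal] <- 1L
    list(pool = out,
         truth = list(focal = focal, carrier_freq = carrier_freq,
                      core_half_len_bp = core_half_len_bp, carriers = carriers))
  })
}

#' Inject genotyping noise
#'
#' Each call is independently set to missing with probability `miss_rate`;
#' each (surviving) homozygous call is flipped to heterozygous with
#' probability `het_error_rate`. Noise applies to the genotype-call layer
#' only; phased haplotypes, if present, are left as simulated.
#'
#' @param ds A [geno_ds].
#' @param miss_rate,het_error_rate Per-call probabilities.
#' @param seed Integer seed.
#' @return The noisy [geno_ds].
#' @export
inject_noise <- function(ds, miss_rate = 0, het_error_rate = 0, seed = NULL) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, het_error_rate >= 0, het_error_rate <= 1)
  with_seed(seed, {
    calls <- ds$calls
    if (het_error_rate > 0) {
      hom <- !is.na(calls) & calls != 1L
      flip <- hom & (matrix(runif(length(calls)), nrow(calls)) < het_error_rate)
      calls[flip] <- 1L
    }
    if (miss_rate > 0) {
      drop <- matrix(runif(length(calls)), nrow(calls)) < miss_rate
      calls[drop] <- NA_integer_
    }
    out <- ds
    out$calls <- calls
    out
  })
}
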