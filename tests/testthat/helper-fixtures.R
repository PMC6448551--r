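# Shared fixture builders; everything generated in code under fixed seeds.

# small phased population on a regular map
tiny_population <- function(n_ind = 30, n_chrom = 2, chrom_mb = 20,
                            spacing_bp = 13600, n_founders = 60, seed = 1,
                            rho = 0.9) {
  map <- sim_map(n_chrom, chrom_mb * 1e6, spacing_bp)
  pool <- sample_founders(n_founders, map, rho = rho, seed = seed)
  assemble_population(pool, n_ind, seed = seed + 500)
}

# genotype dataset from an explicit call matrix on an evenly spaced 1-chrom map
calls_ds <- function(calls, spacing_bp = 13600, chrom = "1") {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  map <- tibble::tibble(chrom = chrom, pos_bp = spacing_bp * seq_len(m),
                        id = paste0("snp", seq_len(m)), ref = "A", alt = "G",
                        anc = "A")
  geno_ds(paste0("s", seq_len(nrow(calls))), map, calls)
}

# Wright's path-counting inbreeding coefficient: an oracle for f_ped().
# F(x) = sum over common ancestors A and over pairs of non-intersecting
# ascending paths sire->A, dam->A of (1/2)^(n1 + n2 + 1) * (1 + F(A)).
path_f <- function(ped, id) {
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)
  paths_up <- function(x) {
    # list of vectors: x, ..., ancestor (self-path included)
    out <- list(x)
    for (p in c(sire[[x]], dam[[x]])) {
      if (!is.na(p)) out <- c(out, lapply(paths_up(p), function(pp) c(x, pp)))
    }
    out
  }
  f_of <- function(x) {
    s <- sire[[x]]; d <- dam[[x]]
    if (is.na(s) || is.na(d)) return(0)
    ps <- paths_up(s); pd <- paths_up(d)
    tot <- 0
    for (a in ps) for (b in pd) {
      anc <- a[length(a)]
      if (anc != b[length(b)]) next
      # paths may share only the common ancestor itself
      if (length(intersect(head(a, -1), head(b, -1))) > 0) next
      tot <- tot + 0.5^(length(a) - 1 + length(b) - 1 + 1) * (1 + f_of(anc))
    }
    tot
  }
  f_of(id)
}

# planted dataset with all machinery downstream of plant_roh exercised once
planted_fixture <- function(fraction = 0.15, n_ind = 30, seed = 3) {
  ds <- tiny_population(n_ind = n_ind, seed = seed)
  plant_roh(ds, fraction, seed = seed + 1)
}
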