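#' Build a pipeline run configuration
#'
#' One object records every stage's inputs and parameters, so a run is fully
#' reproducible from the config and the seed alone. Serializes to/from YAML
#' via [read_run_config()] / [write_run_config()].
#'
#' @param genotypes Path to a VCF (or `ped`/`map` pair via a list
#'   `list(ped=, map=)`); required for every stage.
#' @param pedigree Optional pedigree file path (enables F_PED).
#' @param l_auto_bp Optional autosome-length override.
#' @param qc List: `maf_min`, `sample_genotyped_min`, `autosomes`.
#' @param roh List of [roh_params()] overrides.
#' @param islands List: `top_fraction`.
#' @param ihs List: `enabled`, `maf_min`, `bin_width`, `cm_per_mb`,
#'   `ehh_cutoff`. iHS needs phased input; enabling it without phased
#'   genotypes is a pre-flight error.
#' @param ne List: `alpha`, `max_dist_bp`, `n_bins`, `mapping`, `min_pairs`,
#'   `cm_per_mb`, `max_pairs_per_snp`.
#' @param stages Character vector of stages to run, a subset of
#'   `c("qc", "roh", "inbreeding", "islands", "ihs", "ne")`.
#' @param seed Integer seed applied to every stochastic step.
#' @param out_dir Output directory for the report bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(genotypes, pedigree = NULL, l_auto_bp = NULL,
                       qc = list(), roh = list(), islands = list(),
                       ihs = list(), ne = list(),
                       stages = c("qc", "roh", "inbreeding", "islands", "ne"),
                       seed = 1L, out_dir = tempfile("rohscan_run_")) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) abort(sprintf("unknown %s key(s): %s", where,
                                   paste(bad, collapse = ", ")))
    x
  }
  cfg <- list(
    genotypes = genotypes, pedigree = pedigree, l_auto_bp = l_auto_bp,
    qc = check_keys(qc, c("maf_min", "sample_genotyped_min", "autosomes"), "qc"),
    roh = check_keys(roh, names(roh_params()), "roh"),
    islands = check_keys(islands, "top_fraction", "islands"),
    ihs = check_keys(ihs, c("enabled", "maf_min", "bin_width", "cm_per_mb",
                            "ehh_cutoff"), "ihs"),
    ne = check_keys(ne, c("alpha", "max_dist_bp", "n_bins", "mapping",
                          "min_pairs", "cm_per_mb", "max_pairs_per_snp"), "ne"),
    stages = match.arg(stages, c("qc", "roh", "inbreeding", "islands", "ihs",
                                 "ne"), several.ok = TRUE),
    seed = as.integer(seed), out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("genotypes", "pedigree", "l_auto_bp", "qc", "roh", "islands",
               "ihs", "ne", "stages", "seed", "out_dir")
  bad <- setdiff(names(y), allowed)
  if (length(bad)) abort(paste("unknown config key(s):", paste(bad, collapse = ", ")))
  do.call(run_config, y)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Sequences QC, ROH calling, inbreeding estimation, island/cold-spot
#' detection, the optional iHS scan, and LD-based Ne estimation, writing one
#' TSV per result table plus BED exports and a run log into the config's
#' output directory. Stages not listed in `config$stages` are skipped;
#' requesting a stage whose inputs are missing fails before any computation.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of the in-memory results
#'   (`ds`, `roh`, `roh_summary`, `inbreeding`, `correlations`, `track`,
#'   `islands`, `coldspots`, `ihs`, `ld_bins`, `ne`, plus output paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stages
  # pre-flight
  if (is.character(config$genotypes) && !file.exists(config$genotypes)) {
    abort(paste("genotype file not found:", config$genotypes))
  }
  if ("inbreeding" %in% st && !is.null(config$pedigree) &&
      !file.exists(config$pedigree)) {
    abort(paste("pedigree file not found:", config$pedigree))
  }
  need_roh <- c("roh", "inbreeding", "islands")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("rohscan %s | seed %d | %s",
          as.character(utils::packageVersion("rohscan")), config$seed,
          format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  logline("config: %s", paste(deparse(unclass(config)), collapse = " "))

  ds <- if (is.list(config$genotypes) && !is.null(config$genotypes$ped)) {
    read_plink_text(config$genotypes$ped, config$genotypes$map,
                    l_auto_bp = config$l_auto_bp)
  } else {
    read_vcf(config$genotypes, l_auto_bp = config$l_auto_bp)
  }
  if ("ihs" %in% st && is.null(ds$haps)) {
    abort("iHS stage requested but the genotype input is not fully phased")
  }
  res <- list(ds = ds, out_dir = config$out_dir)
  tsv <- function(x, name) {
    readr::write_tsv(x, file.path(config$out_dir, name), progress = FALSE)
  }
  if ("qc" %in% st) {
    ds <- rlang::exec(filter_variants, ds, !!!config$qc)
    tsv(attr(ds, "qc_log"), "qc_log.tsv")
    tsv(attr(ds, "sample_call_rate"), "sample_call_rate.tsv")
    logline("qc: %d variants kept", n_variants(ds))
    res$ds <- ds
  }
  roh <- NULL
  if (any(need_roh %in% st)) {
    roh <- call_roh(ds, rlang::exec(roh_params, !!!config$roh))
    tsv(tidy(roh), "roh_segments.tsv")
    tsv(summarize_roh(roh), "roh_class_summary.tsv")
    write_bed(roh, file.path(config$out_dir, "roh_segments.bed"))
    logline("roh: %d segments", nrow(roh))
    res$roh <- roh
    res$roh_summary <- summarize_roh(roh)
  }
  if ("inbreeding" %in% st) {
    ped <- if (!is.null(config$pedigree)) read_pedigree(config$pedigree)
    tab <- inbreeding_table(ds = ds, roh = roh, ped = ped,
                            l_auto_bp = config$l_auto_bp)
    tsv(tab, "inbreeding.tsv")
    r <- inbreeding_correlations(tab)
    tsv(tibble::as_tibble(as.data.frame(unclass(r)), rownames = "coefficient"),
        "inbreeding_correlations.tsv")
    res$inbreeding <- tab
    res$correlations <- r
  }
  if ("islands" %in% st) {
    track <- snp_roh_incidence(roh, ds$map)
    isl <- detect_islands(track,
                          config$islands$top_fraction %||% 0.005)
    cold <- detect_coldspots(track)
    tsv(track, "roh_incidence.tsv")
    tsv(isl, "roh_islands.tsv")
    tsv(cold, "roh_coldspots.tsv")
    if (nrow(isl)) write_bed(isl, file.path(config$out_dir, "roh_islands.bed"))
    res$track <- track; res$islands <- isl; res$coldspots <- cold
  }
  if ("ihs" %in% st) {
    ih <- rlang::exec(ihs_scan, ds,
                      !!!config$ihs[setdiff(names(config$ihs), "enabled")])
    tsv(ih, "ihs.tsv")
    res$ihs <- ih
    if (!is.null(res$islands)) {
      res$islands <- island_ihs_summary(res$islands, ih)
      tsv(res$islands, "roh_islands.tsv")
    }
  }
  if ("ne" %in% st) {
    necfg <- config$ne
    pairs <- ld_r2(ds, max_dist_bp = necfg$max_dist_bp %||% 1e7,
                   max_pairs_per_snp = necfg$max_pairs_per_snp,
                   seed = config$seed)
    breaks <- exp(seq(log(5e4), log(necfg$max_dist_bp %||% 1e7),
                      length.out = (necfg$n_bins %||% 50) + 1))
    bins <- bin_ld(pairs, n_samples = n_samples(ds), breaks_bp = breaks,
                   cm_per_mb = necfg$cm_per_mb %||% 1,
                   mapping = necfg$mapping %||% "haldane")
    ne <- ne_trajectory(bins, alpha = necfg$alpha %||% 1,
                        min_pairs = necfg$min_pairs %||% 50)
    tsv(bins, "ld_bins.tsv")
    tsv(ne, "ne_trajectory.tsv")
    res$ld_bins <- bins; res$ne <- ne
  }
  logline("done")
  invisible(res)
}
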