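#' Stable per-stage child seed
#'
#' Fans a single global seed out to independent stage seeds by hashing the
#' stage name, so adding a stage never perturbs the randomness of earlier
#' stages. The result is always a valid 32-bit integer seed.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

#' Build a pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis: input mode (a VCF plus
#' population map, or the synthetic generator), filter thresholds, window
#' parameters, the population comparisons and f4 quartets, permutation
#' counts, optional per-comparison sample caps, sampling-site coordinates
#' for isolation-by-distance, and the global seed.
#'
#' @param mode `"synthetic"` or `"vcf"`.
#' @param seed global integer seed (fans out per stage via [stage_seed()]).
#' @param vcf,pop_map input paths (vcf mode).
#' @param pops,drift_F,topology,admix,ancestral_freq_range simulation model
#'   (synthetic mode); see [population_model()].
#' @param n_sites,n_per_pop,n_lg,lg_length,missing_rate,ld_block_bp
#'   synthetic genotype parameters; see [sample_genotypes()].
#' @param filters named list of [apply_quality_masks()] /
#'   [filter_sites()] thresholds.
#' @param windows named list: `sliding_size`, `sliding_step`,
#'   `sliding_min_sites`, `tile_size`, `tile_min_sites`.
#' @param comparisons list of population pairs for divergence scans.
#' @param f4 list of population quartets (A, B, C, D).
#' @param block_bp f4 jackknife block size in bp.
#' @param nni named list: `quantiles`, `n_perm`.
#' @param ld named list: `pop`, `max_pairs_per_bin`.
#' @param sample_cap optional per-population cap applied to each comparison
#'   via [select_balanced_samples()].
#' @param sites optional data.frame (`code`, `lat`, `lon`) with one row per
#'   population, enabling the Mantel isolation-by-distance stage.
#' @param mantel_n_perm Mantel permutations.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "vcf"), seed = 1,
                       vcf = NULL, pop_map = NULL,
                       pops = c("A", "B", "C", "D"), drift_F = 0.1,
                       topology = "((A,B),(C,D));", admix = list(),
                       ancestral_freq_range = c(0.05, 0.95),
                       n_sites = 5000, n_per_pop = 8, n_lg = 6,
                       lg_length = 5e6, missing_rate = 0.02, ld_block_bp = 0,
                       filters = list(), windows = list(),
                       comparisons = list(c("A", "B"), c("C", "D")),
                       f4 = list(c("A", "B", "C", "D")), block_bp = 5e5,
                       nni = list(), ld = list(), sample_cap = NULL,
                       sites = NULL, mantel_n_perm = 999) {
  mode <- match.arg(mode)
  filters <- utils::modifyList(list(
    snp_qual = 20, geno_qual = 20, map_qual = 20, min_depth = 5,
    high_depth_percentile = 99.5, max_missing_frac = 0.25, min_maf = 0.1,
    biallelic_only = TRUE), filters)
  windows <- utils::modifyList(list(
    sliding_size = 1e6, sliding_step = 1e5, sliding_min_sites = 10,
    tile_size = 1e5, tile_min_sites = 2), windows)
  nni <- utils::modifyList(list(quantiles = c(0.01, 0.05), n_perm = 1000), nni)
  ld <- utils::modifyList(list(pop = pops[1], max_pairs_per_bin = 2000), ld)
  cfg <- list(
    mode = mode, seed = as.integer(seed), vcf = vcf, pop_map = pop_map,
    pops = as.character(pops), drift_F = as.numeric(drift_F),
    topology = topology, admix = admix,
    ancestral_freq_range = as.numeric(ancestral_freq_range),
    n_sites = as.numeric(n_sites), n_per_pop = as.numeric(n_per_pop),
    n_lg = as.integer(n_lg), lg_length = as.numeric(lg_length),
    missing_rate = as.numeric(missing_rate),
    ld_block_bp = as.numeric(ld_block_bp), filters = filters,
    windows = windows, comparisons = lapply(comparisons, as.character),
    f4 = lapply(f4, as.character), block_bp = as.numeric(block_bp),
    nni = nni, ld = ld,
    sample_cap = if (is.null(sample_cap)) NULL else as.integer(sample_cap),
    sites = if (is.null(sites)) NULL else
      data.frame(code = as.character(sites$code), lat = as.numeric(sites$lat),
                 lon = as.numeric(sites$lon), stringsAsFactors = FALSE),
    mantel_n_perm = as.integer(mantel_n_perm)
  )
  if (mode == "vcf" && (is.null(cfg$vcf) || is.null(cfg$pop_map)))
    stop("vcf mode requires 'vcf' and 'pop_map' paths")
  known <- cfg$pops
  if (mode == "synthetic") {
    for (pr in c(cfg$comparisons, cfg$f4)) {
      if (!all(pr %in% known))
        stop("comparison refers to unknown population: ",
             paste(setdiff(pr, known), collapse = ", "))
    }
    if (!ld$pop %in% known) stop("LD population unknown: ", ld$pop)
  }
  for (pr in cfg$comparisons) if (length(pr) != 2) stop("comparisons must be pairs")
  for (pr in cfg$f4) if (length(pr) != 4) stop("f4 entries must be quartets")
  if (any(unlist(cfg[c("n_sites", "n_per_pop", "n_lg", "lg_length")]) <= 0))
    stop("counts must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' `read_run_config(write_run_config(cfg, path))` returns an object equal to
#' `cfg` (round-trip identity).
#'
#' @param path YAML file path.
#' @return `read_run_config`: a validated `run_config`;
#'   `write_run_config`: `path`, invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sites)) {
    raw$sites <- do.call(rbind, lapply(raw$sites, function(s)
      data.frame(code = s$code, lat = s$lat, lon = s$lon,
                 stringsAsFactors = FALSE)))
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @param cfg a [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!is.null(out$sites)) {
    out$sites <- lapply(seq_len(nrow(out$sites)), function(i)
      list(code = out$sites$code[i], lat = out$sites$lat[i],
           lon = out$sites$lon[i]))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Deterministic balanced sample selection
#'
#' Chooses the top `n` samples of a population by a quality rank (higher is
#' better), breaking ties by lexicographic sample id — the rule used to
#' constrain comparisons to even sample numbers.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population label.
#' @param n samples to keep.
#' @param quality_rank optional numeric vector named by sample id; defaults
#'   to the per-sample genotype call rate.
#' @return character vector of `n` sample ids.
#' @export
select_balanced_samples <- function(gm, pop, n, quality_rank = NULL) {
  ids <- gm$samples$id[gm$samples$population == pop]
  if (length(ids) < n)
    stop(sprintf("population '%s' has only %d samples (need %d)",
                 pop, length(ids), n))
  if (is.null(quality_rank)) {
    rows <- match(ids, gm$samples$id)
    quality_rank <- stats::setNames(rowMeans(!is.na(gm$dosage[rows, , drop = FALSE])), ids)
  }
  q <- quality_rank[ids]
  q[is.na(q)] <- -Inf
  ids[order(-q, ids)][seq_len(n)]
}

tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow on either a VCF or synthetic data:
#' simulation (synthetic mode round-trips through VCF writing/reading so the
#' I/O path is exercised), quality masking and site filtering, LD decay
#' profile, sliding-window and nonoverlapping-window FST/DXY scans per
#' comparison (with top-quantile outlier BEDs), the pairwise genome-FST
#' matrix, the f4 table, the NNI clustering report, the Mantel
#' isolation-by-distance report (when site coordinates are configured), and
#' a machine-readable run manifest. Deterministic given the config seed.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  layout <- NULL
  gm <- stage("input", {
    if (cfg$mode == "synthetic") {
      model <- population_model(cfg$pops, cfg$drift_F, topology = cfg$topology,
                                admix_edges = cfg$admix,
                                ancestral_freq_range = cfg$ancestral_freq_range)
      layout <- genome_layout(rep(cfg$lg_length, cfg$n_lg))
      freqs <- simulate_frequencies(model, cfg$n_sites,
                                    stage_seed(cfg$seed, "frequencies"))
      gm0 <- sample_genotypes(freqs, layout, cfg$n_per_pop,
                              missing_rate = cfg$missing_rate,
                              ld_block_bp = cfg$ld_block_bp,
                              seed = stage_seed(cfg$seed, "genotypes"))
      vcf_path <- file.path(out_dir, "synthetic.vcf")
      write_vcf(gm0, vcf_path)
      write_pop_map(gm0$samples, file.path(out_dir, "pop_map.tsv"))
      paths$vcf <- vcf_path
      read_vcf(vcf_path, gm0$samples)
    } else {
      read_vcf(cfg$vcf, cfg$pop_map)
    }
  })
  note("input: %d samples, %d sites", n_samples(gm), n_sites(gm))

  gm <- stage("quality_masks", {
    f <- cfg$filters
    apply_quality_masks(gm, snp_qual = f$snp_qual, geno_qual = f$geno_qual,
                        map_qual = f$map_qual, min_depth = f$min_depth,
                        high_depth_percentile = f$high_depth_percentile)
  })
  note("after quality masks: %d sites, %.2f%% genotypes missing",
       n_sites(gm), 100 * mean(is.na(gm$dosage)))
  gm <- stage("site_filters", {
    f <- cfg$filters
    filter_sites(gm, biallelic_only = f$biallelic_only,
                 max_missing_frac = f$max_missing_frac, min_maf = f$min_maf)
  })
  note("after site filters: %d sites", n_sites(gm))
  if (is.null(layout)) layout <- layout_from_sites(gm)

  paths$panel_summary <- stage("panel_summary", {
    tsv(data.frame(n_samples = n_samples(gm), n_sites = n_sites(gm),
                   n_lg = length(unique(gm$sites$lg)),
                   missing_frac = round(mean(is.na(gm$dosage)), 4)),
        file.path(out_dir, "panel_summary.tsv"))
  })

  paths$ld_profile <- stage("ld_decay", {
    prof <- ld_decay(gm, cfg$ld$pop,
                     max_pairs_per_bin = cfg$ld$max_pairs_per_bin,
                     max_background_pairs = cfg$ld$max_pairs_per_bin,
                     seed = stage_seed(cfg$seed, "ld"))
    out <- prof$bins
    out <- rbind(out, data.frame(bin_start = NA, bin_end = NA,
                                 mean_r2 = prof$background_r2,
                                 n_pairs = prof$background_n))
    tsv(out, file.path(out_dir, "ld_profile.tsv"))
  })

  tile_tables <- list()
  for (pr in cfg$comparisons) {
    nm <- paste(pr, collapse = "_vs_")
    res <- stage(paste0("scan:", nm), {
      gmc <- gm
      if (!is.null(cfg$sample_cap)) {
        keep <- unlist(lapply(pr, function(p)
          select_balanced_samples(gm, p, min(cfg$sample_cap,
                                             sum(gm$samples$population == p)))))
        gmc <- gm_subset(gm, sample_idx = match(keep, gm$samples$id))
      }
      w <- cfg$windows
      sw <- sliding_windows(layout, w$sliding_size, w$sliding_step,
                            w$sliding_min_sites)
      tw <- nonoverlapping_windows(layout, w$tile_size, w$tile_min_sites)
      list(sliding = window_divergence(gmc, pr[1], pr[2], sw),
           tiles = window_divergence(gmc, pr[1], pr[2], tw))
    })
    paths[[paste0("sliding_", nm)]] <-
      tsv(res$sliding, file.path(out_dir, paste0("sliding_", nm, ".tsv")))
    paths[[paste0("tiles_", nm)]] <-
      tsv(res$tiles, file.path(out_dir, paste0("tiles_", nm, ".tsv")))
    tile_tables[[nm]] <- res$tiles
    if (nrow(res$tiles) >= 2) {
      flags <- top_quantile_windows(res$tiles, max(cfg$nni$quantiles))
      bed <- res$tiles[flags, c("lg", "start", "end")]
      paths[[paste0("outliers_", nm)]] <-
        tsv(bed, file.path(out_dir, paste0("outliers_", nm, ".bed")))
    }
  }

  paths$genome_fst <- stage("genome_fst", {
    pops <- unique(gm$samples$population)
    m <- matrix(NA_real_, length(pops), length(pops),
                dimnames = list(pops, pops))
    diag(m) <- 0
    for (i in seq_along(pops)[-length(pops)]) {
      for (j in (i + 1):length(pops)) {
        m[i, j] <- m[j, i] <- suppressWarnings(
          genome_fst(gm, pops[i], pops[j], layout = layout,
                     window_size = cfg$windows$tile_size,
                     min_sites = cfg$windows$tile_min_sites))
      }
    }
    tsv(cbind(data.frame(population = rownames(m)), as.data.frame(m)),
        file.path(out_dir, "genome_fst_matrix.tsv"))
  })

  paths$f4_table <- stage("f4", {
    rows <- lapply(cfg$f4, function(qd) {
      r <- f4_test(gm, qd[1], qd[2], qd[3], qd[4], block_bp = cfg$block_bp)
      data.frame(A = qd[1], B = qd[2], C = qd[3], D = qd[4], f4 = r$f4,
                 SEM = r$sem, Z = r$z, p = r$p, n_blocks = r$n_blocks,
                 n_sites = r$n_sites, stringsAsFactors = FALSE)
    })
    tsv(do.call(rbind, rows), file.path(out_dir, "f4_table.tsv"))
  })

  paths$nni_report <- stage("nni", {
    usable <- tile_tables[vapply(tile_tables, nrow, integer(1)) >= 2]
    rep_ <- nni_report_all(usable, quantiles = cfg$nni$quantiles,
                           n_perm = cfg$nni$n_perm,
                           seed = stage_seed(cfg$seed, "nni"))
    tsv(rep_, file.path(out_dir, "nni_report.tsv"))
  })

  if (!is.null(cfg$sites)) {
    paths$mantel_report <- stage("mantel", {
      fstm <- as.matrix(utils::read.table(file.path(out_dir, "genome_fst_matrix.tsv"),
                                          sep = "\t", header = TRUE,
                                          row.names = 1, check.names = FALSE))
      common <- intersect(rownames(fstm), cfg$sites$code)
      geo <- geo_distance_matrix(cfg$sites[match(common, cfg$sites$code), ])
      mt <- mantel_test(fstm[common, common], geo,
                        n_perm = cfg$mantel_n_perm,
                        seed = stage_seed(cfg$seed, "mantel"))
      tsv(data.frame(r = mt$r, p = mt$p, n = mt$n, n_perm = mt$n_perm,
                     seed = mt$seed),
          file.path(out_dir, "mantel_report.tsv"))
    })
  }

  paths$manifest <- stage("manifest", {
    manifest <- list(
      package = "popgenscan",
      version = as.character(utils::packageVersion("popgenscan")),
      seed = cfg$seed, mode = cfg$mode, filters = cfg$filters,
      windows = cfg$windows, block_bp = cfg$block_bp, nni = cfg$nni,
      log = log_lines
    )
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE)
    p
  })
  invisible(paths)
}
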