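#' Run the full range-expansion analysis pipeline
#'
#' Orchestrates filter -> summary statistics -> F_ST/PCA -> distances ->
#' regressions -> psi -> locus classifiers -> outlier scans -> overlap
#' table, writing one directory of TSV/JSON outputs plus a run manifest
#' (package version, seeds, config hash). Outputs are deterministic given
#' the same config and seeds. Stages whose inputs are absent (e.g. no ocean
#' grid) are skipped and logged in the manifest.
#'
#' @param cfg named list (or path to a JSON file) with elements:
#'   `vcf`, `popmap` (paths) or `gm`, `pm` (objects); `filter` (list passed
#'   to [filter_config()], or `NULL` to skip filtering); `origin_pop`;
#'   `grid` (ocean_grid or `NULL`); `waypoint_sites`, `waypoints`;
#'   `psi` (list: `subsample_n`, `polarization`); `fst` (list: `n_perm`,
#'   `alpha`); `outliers` (list: `target_fst`, `n_sims`, `fdr`, `top_frac`);
#'   `minmax_thresholds`; `seed`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  log <- character(0)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  gm <- stage("load", {
    if (!is.null(cfg$gm)) cfg$gm else read_vcf(cfg$vcf)
  })
  pm <- stage("load", {
    if (!is.null(cfg$pm)) cfg$pm else read_popmap(cfg$popmap)
  })

  if (!is.null(cfg$filter)) {
    fc <- stage("filter", do.call(filter_config, cfg$filter))
    gm <- stage("filter", apply_locus_filters(gm, pm, fc))
    log <- c(log, sprintf("filter: retained %d loci", ncol(gm$calls)))
  } else log <- c(log, "filter: skipped (no filter config)")

  res$summary <- stage("sumstats", summary_table(gm, pm))
  write_tsv_commented(res$summary, file.path(out_dir, "summary_table.tsv"),
                      list(seed = seed))
  lps <- stage("sumstats", locus_pop_stats(gm, pm))
  write_tsv_commented(lps, file.path(out_dir, "locus_pop_stats.tsv"),
                      list(seed = seed))

  fst_cfg <- cfg$fst
  if (is.null(fst_cfg)) fst_cfg <- list()
  res$fst <- stage("fst", fst_matrix(gm, pm,
                                     n_perm = fst_cfg$n_perm %||% 99,
                                     alpha = fst_cfg$alpha %||% 0.05,
                                     seed = .sub_seed(seed, 11)))
  th <- res$fst$theta
  star <- ifelse(res$fst$significant, "*", "")
  fst_out <- data.frame(pop = rownames(th),
                        matrix(sprintf("%.6g%s", th, star), nrow(th),
                               dimnames = list(NULL, colnames(th))),
                        check.names = FALSE)
  write_tsv_commented(fst_out, file.path(out_dir, "fst_matrix.tsv"),
                      list(seed = seed, n_perm = fst_cfg$n_perm %||% 99,
                           bonferroni_alpha = res$fst$bonferroni_alpha))

  res$pca <- stage("pca", pca(gm))
  write_tsv_commented(data.frame(sample = rownames(res$pca$coords),
                                 res$pca$coords, check.names = FALSE),
                      file.path(out_dir, "pca_coords.tsv"), list(seed = seed))
  write_tsv_commented(data.frame(axis = seq_along(res$pca$percent_variance),
                                 percent_variance = res$pca$percent_variance),
                      file.path(out_dir, "pca_eigen.tsv"), list(seed = seed))

  gradient <- NULL
  if (!is.null(cfg$grid) && !is.null(cfg$origin_pop) && !is.null(pm$coords)) {
    res$distances <- stage("distance",
      distance_table(cfg$grid, pm$coords, cfg$origin_pop,
                     waypoint_sites = cfg$waypoint_sites %||% character(0),
                     waypoints = cfg$waypoints))
    write_tsv_commented(res$distances, file.path(out_dir, "distances.tsv"),
                        list(origin = cfg$origin_pop))
    gradient <- res$distances
    regs <- lapply(c("obs_het_mean", "exp_het_mean", "allelic_richness"),
                   function(colname) {
      r <- diversity_distance_regression(
        stats::setNames(res$summary[[colname]], res$summary$pop), gradient)
      data.frame(statistic = colname, slope = r$slope, intercept = r$intercept,
                 r_squared = r$r_squared, p_value = r$p_value, n = r$n)
    })
    res$regressions <- do.call(rbind, regs)
    write_tsv_commented(res$regressions, file.path(out_dir, "regressions.tsv"),
                        list(origin = cfg$origin_pop, distance = "modified_km"))
  } else log <- c(log, "distance/regression: skipped (no grid, origin or coords)")

  psi_cfg <- cfg$psi
  if (is.null(psi_cfg)) psi_cfg <- list()
  res$psi <- stage("psi", psi_matrix_and_ranking(
    gm, pm, subsample_n = psi_cfg$subsample_n %||% 10,
    polarization = psi_cfg$polarization %||% "dataset_minor",
    seed = .sub_seed(seed, 21)))
  write_tsv_commented(data.frame(pop = rownames(res$psi$psi), res$psi$psi,
                                 check.names = FALSE),
                      file.path(out_dir, "psi_matrix.tsv"),
                      list(seed = seed, subsample_n = res$psi$subsample_n,
                           polarization = res$psi$polarization))
  write_tsv_commented(res$psi$ranking, file.path(out_dir, "psi_ranking.tsv"),
                      list(seed = seed))

  res$profiles <- stage("locus_filters", frequency_profiles(gm, pm))
  ff <- flip_flop_loci(res$profiles)
  thresholds <- cfg$minmax_thresholds %||% c(0.5, 0.6, 0.7, 0.8, 0.9)
  mm <- lapply(thresholds, function(th) minmax_diff_loci(res$profiles, th))
  names(mm) <- sprintf("diff_%.1f", thresholds)
  sets <- c(list(flip_flop = ff), mm)
  for (nm in names(sets))
    write_tsv_commented(data.frame(locus_id = sets[[nm]]),
                        file.path(out_dir, paste0("loci_", nm, ".tsv")),
                        list(classifier = nm))

  out_cfg <- cfg$outliers
  if (is.null(out_cfg)) out_cfg <- list()
  env <- stage("outliers", build_null_envelope(
    gm, pm, target_fst = out_cfg$target_fst %||% 0.05,
    n_sims = out_cfg$n_sims %||% 1e5,
    seed = .sub_seed(seed, 31)))
  res$fst_outliers <- stage("outliers",
    fst_outliers(gm, pm, env, fdr = out_cfg$fdr %||% 0.01))
  write_tsv_commented(res$fst_outliers, file.path(out_dir, "fst_outliers.tsv"),
                      list(seed = seed, target_fst = env$target_fst,
                           n_sims = env$n_sims, fdr = out_cfg$fdr %||% 0.01))
  sets$fst_outlier <- res$fst_outliers$locus_id[res$fst_outliers$outlier]

  if (!is.null(gradient)) {
    sc <- stage("outliers", env_assoc_scores(gm, pm, gradient))
    sel <- stage("outliers", empirical_rank_bins(
      sc, top_frac = out_cfg$top_frac %||% 0.05, seed = .sub_seed(seed, 41)))
    res$env_outliers <- sel
    write_tsv_commented(sel$detail, file.path(out_dir, "env_outliers.tsv"),
                        list(seed = seed, top_frac = out_cfg$top_frac %||% 0.05))
    sets$env_outlier <- sel$selected
  } else log <- c(log, "env outlier scan: skipped (no distance gradient)")

  res$overlap <- stage("overlap", overlap_table(sets))
  write_tsv_commented(data.frame(set = rownames(res$overlap$intersection),
                                 res$overlap$intersection, check.names = FALSE),
                      file.path(out_dir, "overlap_table.tsv"),
                      list(sets = paste(names(sets), collapse = ",")))

  manifest <- list(
    package = "edgefront",
    version = as.character(utils::packageVersion("edgefront")),
    seed = seed,
    config_hash = .config_hash(cfg),
    stages_log = log,
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(cfg) {
  cfg$gm <- NULL; cfg$pm <- NULL; cfg$grid <- NULL
  ser <- as.double(serialize(cfg, NULL, version = 2))
  # positional checksum; a stable fingerprint without a digest dependency
  h <- sum(ser * ((seq_along(ser) - 1) %% 251 + 1)) %% 2147483647
  sprintf("%d-%d", length(ser), as.integer(h))
}
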