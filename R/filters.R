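#' Locus-retention filter configuration
#'
#' Mirrors the retention rules of the Stacks `populations` program: a locus
#' is kept when it is "present" in at least `min_populations` populations,
#' where presence in a population requires the fraction of genotyped
#' individuals there to be at least `min_fraction_individuals` (both
#' thresholds inclusive). Optionally one SNP per RAD tag is retained, chosen
#' uniformly at random under `seed`.
#'
#' @param min_populations integer, the `-p` rule.
#' @param min_fraction_individuals fraction in (0, 1], the `-r` rule.
#' @param one_snp_per_tag keep a single random SNP per tag
#'   (`--write_random_snp`).
#' @param seed integer seed for the per-tag SNP choice.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(min_populations = 8L, min_fraction_individuals = 0.8,
                          one_snp_per_tag = TRUE, seed = 1L) {
  if (min_fraction_individuals <= 0 || min_fraction_individuals > 1)
    .stopf("min_fraction_individuals must be in (0, 1]")
  if (min_populations < 1) .stopf("min_populations must be >= 1")
  structure(list(min_populations = as.integer(min_populations),
                 min_fraction_individuals = min_fraction_individuals,
                 one_snp_per_tag = isTRUE(one_snp_per_tag),
                 seed = as.integer(seed)),
            class = "filter_config")
}

#' Apply locus-retention filters
#'
#' @param gm genotype_matrix.
#' @param pm population_map; every sample in `gm` must be mapped.
#' @param cfg filter_config.
#' @return filtered genotype_matrix with `attr(, "filter_meta")` holding the
#'   config and per-stage locus counts.
#' @export
apply_locus_filters <- function(gm, pm, cfg = filter_config()) {
  check_popmap(gm, pm, strict = FALSE) |> suppressWarnings()
  if (cfg$min_populations > length(pm$pops))
    .stopf("min_populations (%d) exceeds number of populations (%d)",
           cfg$min_populations, length(pm$pops))
  rows <- .pop_rows(gm, pm)
  rows <- rows[lengths(rows) > 0]
  # population x locus matrix of "presence": genotyped fraction >= r
  pres <- vapply(rows, function(idx) {
    ng <- colSums(!is.na(gm$calls[idx, , drop = FALSE]))
    ng >= 1L & (ng / length(idx)) >= cfg$min_fraction_individuals
  }, logical(ncol(gm$calls)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1)  # single-locus edge
  keep <- rowSums(pres) >= cfg$min_populations
  n_pr <- sum(keep)
  if (!any(keep)) .stopf("no loci survive the -p/-r filters")
  idx <- which(keep)
  if (cfg$one_snp_per_tag) {
    tags <- gm$loci$tag_id[idx]
    idx_by_tag <- split(idx, tags)
    idx_by_tag <- idx_by_tag[order(names(idx_by_tag))]  # platform-stable order
    idx <- with_seed(cfg$seed, vapply(idx_by_tag, function(v) {
      v[sample.int(length(v), 1L)]
    }, integer(1)))
    idx <- sort(unname(idx))
  }
  out <- gm_subset(gm, loci = idx)
  attr(out, "filter_meta") <- list(config = unclass(cfg),
                                   n_input = ncol(gm$calls),
                                   n_after_presence = n_pr,
                                   n_retained = length(idx))
  out
}
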