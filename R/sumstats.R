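# Per-locus, per-population diversity statistics.
#
# Conventions (pinned by tests):
#  * p is the reference-allele frequency at the locus in the population;
#  * H_I = fraction of heterozygous genotyped individuals;
#  * H_S = 2pq; pi = (n/(n-1)) * 2pq with n = gene copies (unbiased gene
#    diversity, the Stacks convention);
#  * F_IS = (H_S - H_I)/H_S, undefined (NA) when H_S = 0 -- undefined values
#    are excluded from means and distributions, never coerced to 0.

# population x loci stat matrices for the mapped samples
.pop_locus_engine <- function(gm, pm) {
  rows <- .pop_rows(gm, pm)
  pops <- names(rows)
  nl <- ncol(gm$calls)
  mk <- function() matrix(NA_real_, length(pops), nl, dimnames = list(pops, gm$loci$locus_id))
  n_ind <- mk(); p_alt <- mk(); h_obs <- mk()
  for (k in seq_along(pops)) {
    sub <- gm$calls[rows[[k]], , drop = FALSE]
    ng <- colSums(!is.na(sub))
    n_ind[k, ] <- ng
    tot <- colSums(sub, na.rm = TRUE)
    p_alt[k, ] <- ifelse(ng > 0, tot / (2 * ng), NA_real_)
    h_obs[k, ] <- ifelse(ng > 0, colSums(sub == 1L, na.rm = TRUE) / ng, NA_real_)
  }
  list(pops = pops, n_ind = n_ind, p_alt = p_alt, h_obs = h_obs)
}

#' Per-locus, per-population summary statistics
#'
#' @param gm genotype_matrix.
#' @param pm population_map.
#' @param pop population label; `NULL` returns all populations.
#' @param locus locus ID; `NULL` returns all loci.
#' @return data.frame with columns `locus_id`, `pop`, `n_ind`, `n` (gene
#'   copies), `p` (reference-allele frequency), `q`, `h_obs`, `h_exp`, `pi`,
#'   `fis` (`NA` when undefined, i.e. `h_exp == 0`). Rows with zero genotyped
#'   individuals are returned with `n = 0` and all statistics `NA`.
#' @export
locus_pop_stats <- function(gm, pm, pop = NULL, locus = NULL) {
  eng <- .pop_locus_engine(gm, pm)
  pops <- if (is.null(pop)) eng$pops else pop
  if (!all(pops %in% eng$pops)) .stopf("unknown population")
  lidx <- if (is.null(locus)) seq_len(ncol(gm$calls)) else match(locus, gm$loci$locus_id)
  if (anyNA(lidx)) .stopf("unknown locus")
  out <- do.call(rbind, lapply(pops, function(pp) {
    ni <- eng$n_ind[pp, lidx]
    pa <- eng$p_alt[pp, lidx]
    hi <- eng$h_obs[pp, lidx]
    n <- 2 * ni
    p <- 1 - pa                       # ref-oriented
    hs <- 2 * p * (1 - p)
    pi <- ifelse(n > 1, n / (n - 1) * hs, NA_real_)
    fis <- ifelse(!is.na(hs) & hs > 0, (hs - hi) / hs, NA_real_)
    data.frame(locus_id = gm$loci$locus_id[lidx], pop = pp,
               n_ind = as.integer(ni), n = as.integer(n),
               p = p, q = 1 - p, h_obs = hi, h_exp = hs, pi = pi, fis = fis,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rarefied allelic richness at a locus
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, by hypergeometric rarefaction:
#' sum over alleles of `1 - choose(N - N_a, g)/choose(N, g)`.
#'
#' @param allele_counts numeric vector of allele counts (gene copies per
#'   allele) in one population at one locus.
#' @param g rarefaction size in gene copies; must satisfy `g <= sum(counts)`.
#' @return expected allele count.
#' @export
rarefied_richness <- function(allele_counts, g) {
  N <- sum(allele_counts)
  if (g < 1 || g > N) .stopf("g must be in [1, total gene copies]")
  sum(1 - exp(lchoose(N - allele_counts, g) - lchoose(N, g)))
}

#' Population-level summary (one Table-1-style row)
#'
#' Means are taken over loci with data in the population. Private alleles
#' are alleles observed (count > 0) in this population and in no other.
#' Rarefied richness uses, per locus, the smallest gene-copy count across
#' populations with data at that locus, and is then averaged over loci.
#'
#' @param gm genotype_matrix (typically after [apply_locus_filters()]).
#' @param pm population_map.
#' @param pop population label.
#' @param major `"global"` (default): mean P is the mean per-population
#'   frequency of the dataset-wide major allele; `"local"`: per-population
#'   major allele.
#' @return one-row data.frame with columns `pop`, `n`, `n_genotyped_mean`,
#'   `private`, `p_major_mean`, `obs_het_mean`, `exp_het_mean`, `pi_mean`,
#'   `fis_mean`, `allelic_richness`.
#' @export
population_summary <- function(gm, pm, pop, major = c("global", "local")) {
  major <- match.arg(major)
  eng <- .pop_locus_engine(gm, pm)
  if (!pop %in% eng$pops) .stopf("unknown population: %s", pop)
  n_samples <- sum(pm$pop[gm$samples] == pop)
  if (n_samples == 0) .stopf("population %s has zero samples", pop)
  ni <- eng$n_ind[pop, ]
  has <- ni > 0
  pa <- eng$p_alt[pop, ]
  p_ref <- 1 - pa
  hs <- 2 * p_ref * (1 - p_ref)
  n <- 2 * ni
  pi <- ifelse(n > 1, n / (n - 1) * hs, NA_real_)
  fis <- ifelse(hs > 0, (hs - eng$h_obs[pop, ]) / hs, NA_real_)

  # dataset-wide major allele per locus (tie at 0.5 -> ref)
  tot_copies <- colSums(2 * eng$n_ind)
  alt_copies <- colSums(2 * eng$n_ind * eng$p_alt, na.rm = TRUE)
  ref_freq_global <- 1 - alt_copies / tot_copies
  major_is_ref <- ref_freq_global >= 0.5
  p_major <- if (major == "global") ifelse(major_is_ref, p_ref, pa)
             else pmax(p_ref, pa)

  # private alleles: allele count > 0 here and 0 in every other population
  alt_cnt <- 2 * eng$n_ind * eng$p_alt
  ref_cnt <- 2 * eng$n_ind * (1 - eng$p_alt)
  alt_cnt[is.na(alt_cnt)] <- 0; ref_cnt[is.na(ref_cnt)] <- 0
  here <- which(eng$pops == pop)
  others_alt <- colSums(alt_cnt[-here, , drop = FALSE])
  others_ref <- colSums(ref_cnt[-here, , drop = FALSE])
  private <- sum(alt_cnt[here, ] > 0 & others_alt == 0) +
             sum(ref_cnt[here, ] > 0 & others_ref == 0)

  # rarefied richness with g = min gene copies across populations with data
  g_locus <- apply(2 * eng$n_ind, 2, function(v) {
    v <- v[v > 0]; if (length(v)) min(v) else NA_real_
  })
  ar <- vapply(which(has & !is.na(g_locus)), function(j) {
    rarefied_richness(c(ref_cnt[here, j], alt_cnt[here, j])[
      c(ref_cnt[here, j], alt_cnt[here, j]) > 0], g_locus[j])
  }, numeric(1))

  data.frame(pop = pop, n = n_samples,
             n_genotyped_mean = mean(ni[has]),
             private = as.integer(private),
             p_major_mean = mean(p_major[has], na.rm = TRUE),
             obs_het_mean = mean(eng$h_obs[pop, has]),
             exp_het_mean = mean(hs[has]),
             pi_mean = mean(pi[has], na.rm = TRUE),
             fis_mean = mean(fis[has], na.rm = TRUE),
             allelic_richness = mean(ar),
             stringsAsFactors = FALSE)
}

#' Summary table for all populations (Table-1 shape)
#' @inheritParams population_summary
#' @return data.frame, one row per population.
#' @export
summary_table <- function(gm, pm, major = "global") {
  out <- do.call(rbind, lapply(pm$pops, function(p)
    population_summary(gm, pm, p, major = major)))
  rownames(out) <- NULL
  out
}

# shared binning: left-closed equal bins on [lo, hi], last bin right-closed
.bin_proportions <- function(x, lo, hi, n_bins) {
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  out <- data.frame(bin_left = breaks[-length(breaks)], bin_right = breaks[-1])
  if (length(x) == 0) {
    out$proportion <- NA_real_
    attr(out, "empty") <- TRUE
    return(out)
  }
  i <- findInterval(x, breaks, rightmost.closed = TRUE)
  i[i < 1] <- 1L; i[i > n_bins] <- n_bins
  out$proportion <- tabulate(i, n_bins) / length(x)
  attr(out, "empty") <- FALSE
  out
}

#' Binned F_IS distribution
#'
#' Ten (by default) equal, left-closed bins on `[-1, 1]` (last bin closed on
#' the right). Undefined F_IS records (expected heterozygosity zero) are
#' dropped before binning; if none remain the distribution is returned empty
#' with `attr(, "empty") = TRUE` and a warning.
#'
#' @param stats data.frame from [locus_pop_stats()] (uses its `fis` column),
#'   or a numeric vector of F_IS values.
#' @param n_bins number of bins.
#' @return data.frame `bin_left`, `bin_right`, `proportion`.
#' @export
fis_distribution <- function(stats, n_bins = 10) {
  x <- if (is.data.frame(stats)) stats$fis else stats
  x <- x[!is.na(x)]
  if (!length(x)) .warnf("all F_IS values undefined; empty distribution")
  .bin_proportions(x, -1, 1, n_bins)
}

#' Binned major-allele (or folded minor-allele) frequency spectrum
#'
#' Per-locus per-population major-allele frequency binned on `[0.5, 1]`, or
#' with `folded = TRUE` the minor-allele frequency binned on `[0, 0.5]`.
#'
#' @param gm genotype_matrix.
#' @param pm population_map.
#' @param pop population label.
#' @param n_bins number of bins.
#' @param folded bin the minor-allele frequency instead.
#' @return data.frame `bin_left`, `bin_right`, `proportion`.
#' @export
folded_sfs <- function(gm, pm, pop, n_bins = 10, folded = FALSE) {
  eng <- .pop_locus_engine(gm, pm)
  if (!pop %in% eng$pops) .stopf("unknown population: %s", pop)
  pa <- eng$p_alt[pop, ]
  pa <- pa[!is.na(pa)]
  maj <- pmax(pa, 1 - pa)
  if (folded) .bin_proportions(1 - maj, 0, 0.5, n_bins)
  else .bin_proportions(maj, 0.5, 1, n_bins)
}
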