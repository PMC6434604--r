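#' Per-locus major-allele frequency profiles across populations
#'
#' For each locus, the dataset-wide major allele is the allele most frequent
#' over all genotyped samples (a tie at exactly 0.5 resolves to the
#' reference allele, logged via `message()`); the profile records that
#' allele's frequency in each population (missing-aware) plus the min, max
#' and range over populations with data.
#'
#' @param gm genotype_matrix.
#' @param pm population_map.
#' @return data.frame: `locus_id`, `major_allele` (`"ref"`/`"alt"`), one
#'   `freq_<pop>` column per population, `min_freq`, `max_freq`, `range`.
#' @export
frequency_profiles <- function(gm, pm) {
  eng <- .pop_locus_engine(gm, pm)
  tot <- colSums(2 * eng$n_ind)
  alt <- colSums(2 * eng$n_ind * eng$p_alt, na.rm = TRUE)
  ref_freq <- 1 - alt / tot
  ties <- sum(abs(ref_freq - 0.5) < 1e-12)
  if (ties > 0)
    message(sprintf("frequency_profiles: %d locus/loci tied at 0.5; major set to ref", ties))
  major_is_ref <- ref_freq >= 0.5
  fmat <- ifelse(matrix(major_is_ref, nrow(eng$p_alt), ncol(eng$p_alt), byrow = TRUE),
                 1 - eng$p_alt, eng$p_alt)     # pops x loci, freq of major allele
  dimnames(fmat) <- dimnames(eng$p_alt)
  mn <- apply(fmat, 2, min, na.rm = TRUE)
  mx <- apply(fmat, 2, max, na.rm = TRUE)
  out <- data.frame(locus_id = gm$loci$locus_id,
                    major_allele = ifelse(major_is_ref, "ref", "alt"),
                    stringsAsFactors = FALSE)
  for (p in eng$pops) out[[paste0("freq_", p)]] <- fmat[p, ]
  out$min_freq <- mn
  out$max_freq <- mx
  out$range <- mx - mn
  out
}

#' Flip-flop loci
#'
#' Loci whose dataset-wide major allele is locally the minor allele in at
#' least one population: minimum per-population frequency strictly below
#' 0.5 ("drops below" is strict; a population at exactly 0.5 does not flag).
#'
#' @param profiles data.frame from [frequency_profiles()].
#' @return character vector of locus IDs.
#' @export
flip_flop_loci <- function(profiles) {
  profiles$locus_id[profiles$min_freq < 0.5]
}

#' Loci exceeding a min-max frequency difference
#'
#' @param profiles data.frame from [frequency_profiles()].
#' @param threshold difference threshold (the study scanned 0.5-0.9).
#' @param inclusive treat the threshold as `>=` (default, "at least");
#'   `FALSE` uses strict `>` ("exceeded").
#' @return character vector of locus IDs.
#' @export
minmax_diff_loci <- function(profiles, threshold, inclusive = TRUE) {
  sel <- if (inclusive) profiles$range >= threshold else profiles$range > threshold
  profiles$locus_id[sel]
}

#' Loci with excess major-allele frequency in a central population
#'
#' Within `locus_set`, counts loci whose major-allele frequency is strictly
#' greater in the center population than in the edge population.
#'
#' @param profiles data.frame from [frequency_profiles()].
#' @param center_pop,edge_pop population labels.
#' @param locus_set character vector of locus IDs to restrict to.
#' @return list `count`, `loci`.
#' @export
center_edge_excess <- function(profiles, center_pop, edge_pop, locus_set) {
  sub <- profiles[profiles$locus_id %in% locus_set, ]
  fc <- sub[[paste0("freq_", center_pop)]]
  fe <- sub[[paste0("freq_", edge_pop)]]
  if (is.null(fc) || is.null(fe)) .stopf("unknown population")
  sel <- !is.na(fc) & !is.na(fe) & fc > fe
  list(count = sum(sel), loci = sub$locus_id[sel])
}

#' Pairwise overlap accounting between named locus sets
#'
#' @param sets named list of character vectors of locus IDs.
#' @return list with matrices `intersection` (`|A | B|` counts, diagonal
#'   `|A|`) and `only` (`|A \\ B|`, row set minus column set).
#' @export
overlap_table <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    .stopf("sets must be a fully named list")
  k <- length(sets)
  inter <- matrix(0L, k, k, dimnames = list(names(sets), names(sets)))
  only <- inter
  for (i in seq_len(k)) for (j in seq_len(k)) {
    inter[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    only[i, j] <- length(setdiff(sets[[i]], sets[[j]]))
  }
  list(intersection = inter, only = only)
}
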