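# Forward-time serial founder-event simulator.
#
# The generator works on per-locus allele frequencies (unlinked SNPs, the
# same assumption the analysis makes) rather than a sequence-level
# coalescent: each colonised deme evolves by Wright-Fisher binomial drift,
# demes are founded in order by small binomial founder samples from the
# previously colonised deme, census size grows logistically to carrying
# capacity, and adjacent colonised demes exchange migrants each generation.
# Allele surfing arises from drift alone; there is no selection.

#' Configuration for the serial founder-event simulator
#'
#' Defaults state the world the analysis assumes: nine demes along an
#' invasion pathway, ~1.2e4 biallelic loci, small founder sizes with rapid
#' post-founding logistic growth, weak migration between adjacent demes,
#' per-deme sample sizes matching the study's sampling design (7-20
#' diploids), and 5% missing genotypes.
#'
#' @param n_demes number of demes.
#' @param n_loci number of biallelic loci.
#' @param founder_size diploid founders per colonisation event.
#' @param carrying_capacity diploid carrying capacity per deme.
#' @param growth_rate logistic growth rate per generation.
#' @param migration_rate per-generation exchange fraction with each
#'   adjacent colonised deme.
#' @param gens_between generations between successive colonisation events.
#' @param gens_after generations after the last colonisation.
#' @param samples_per_deme diploids sampled per deme (recycled to
#'   `n_demes`).
#' @param missing_rate per-call missing probability.
#' @param wahlund_fst0 within-deme patch (reef/cohort) differentiation at
#'   the moment of founding. Sampled individuals in each deme come from two
#'   internal patches whose frequencies diverge from the deme mean by a
#'   Balding-Nichols draw at `F = wahlund_fst0 * exp(-(t - t_col)/
#'   wahlund_tau)`; recently founded (edge) demes therefore carry a
#'   Wahlund-style heterozygote deficit (positive F_IS) that decays as
#'   demes age and mix, the disequilibrium gradient reported for real
#'   invasion fronts. Set to 0 for panmictic demes.
#' @param wahlund_tau decay time of patch structure, generations.
#' @param colonization_order permutation of `1:n_demes`; the first entry is
#'   the origin.
#' @param deme_spacing_km geographic spacing of demes along the pathway.
#' @param ancestral `"one_over_x"` (density proportional to 1/x truncated to
#'   `[1/(2K), 1 - 1/(2K)]`) or `"beta"`.
#' @param beta_shape1,beta_shape2 shapes for `ancestral = "beta"`.
#' @param seed integer seed.
#' @return object of class `expansion_config`.
#' @export
expansion_config <- function(n_demes = 9, n_loci = 12000, founder_size = 10,
                             carrying_capacity = 500, growth_rate = 0.7,
                             migration_rate = 0.01, gens_between = 5,
                             gens_after = 5,
                             samples_per_deme = c(11, 9, 11, 14, 16, 7, 20, 15, 16),
                             missing_rate = 0.05, wahlund_fst0 = 0.15,
                             wahlund_tau = 20,
                             colonization_order = seq_len(n_demes),
                             deme_spacing_km = 500,
                             ancestral = c("one_over_x", "beta"),
                             beta_shape1 = 0.8, beta_shape2 = 0.8,
                             seed = 1L) {
  ancestral <- match.arg(ancestral)
  if (founder_size > carrying_capacity)
    .stopf("founder_size must be <= carrying_capacity")
  if (!identical(sort(colonization_order), seq_len(n_demes)))
    .stopf("colonization_order must be a permutation of 1:n_demes")
  if (migration_rate < 0 || migration_rate > 1 || missing_rate < 0 ||
      missing_rate > 1 || wahlund_fst0 < 0 || wahlund_fst0 >= 1)
    .stopf("rates must be in [0, 1]")
  structure(list(n_demes = n_demes, n_loci = n_loci,
                 founder_size = founder_size,
                 carrying_capacity = carrying_capacity,
                 growth_rate = growth_rate, migration_rate = migration_rate,
                 gens_between = gens_between, gens_after = gens_after,
                 samples_per_deme = rep_len(samples_per_deme, n_demes),
                 missing_rate = missing_rate,
                 wahlund_fst0 = wahlund_fst0, wahlund_tau = wahlund_tau,
                 colonization_order = colonization_order,
                 deme_spacing_km = deme_spacing_km,
                 ancestral = ancestral,
                 beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
                 seed = as.integer(seed)),
            class = "expansion_config")
}

.draw_ancestral <- function(cfg, n) {
  if (cfg$ancestral == "one_over_x") {
    a <- 1 / (2 * cfg$carrying_capacity)
    b <- 1 - a
    a * exp(stats::runif(n) * log(b / a))
  } else {
    stats::rbeta(n, cfg$beta_shape1, cfg$beta_shape2)
  }
}

# sample diploid genotypes with missingness; returns samples x loci matrix
.sample_genotypes <- function(freqs_by_deme, n_per_deme, missing_rate, labels) {
  mats <- lapply(seq_along(freqs_by_deme), function(d) {
    n <- n_per_deme[d]
    f <- freqs_by_deme[[d]]
    m <- matrix(stats::rbinom(n * length(f), 2, rep(f, each = n)), nrow = n)
    if (missing_rate > 0)
      m[stats::runif(length(m)) < missing_rate] <- NA_integer_
    rownames(m) <- sprintf("%s_%02d", labels[d], seq_len(n))
    m
  })
  do.call(rbind, mats)
}

.build_sim_output <- function(calls, cfg_like, pops_of_sample, positions_km, truth) {
  nl <- ncol(calls)
  loci <- data.frame(locus_id = sprintf("L%05d", seq_len(nl)),
                     tag_id = sprintf("T%05d", seq_len(nl)),
                     pos = 10L, ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
  colnames(calls) <- loci$locus_id
  gm <- genotype_matrix(calls, loci)
  pops <- unique(unname(pops_of_sample))
  coords <- data.frame(pop = pops, lat = 0,
                       lon = positions_km / 111.32,  # km along the equator
                       stringsAsFactors = FALSE)
  pm <- population_map(pops_of_sample, coords)
  list(gm = gm, pm = pm, truth = truth)
}

#' Simulate a serial founder-event range expansion
#'
#' @param cfg expansion_config.
#' @return list `gm` (genotype_matrix), `pm` (population_map with sites
#'   spaced along a line), `truth` (class `sim_truth`: origin deme label,
#'   colonisation order and times, deme positions, config echo, seed).
#' @export
simulate_expansion <- function(cfg = expansion_config()) {
  out <- with_seed(cfg$seed, {
    nd <- cfg$n_demes; nl <- cfg$n_loci
    labels <- sprintf("D%d", seq_len(nd))
    f <- matrix(NA_real_, nd, nl)
    N <- integer(nd)
    colonized <- logical(nd)
    ord <- cfg$colonization_order
    col_time <- rep(NA_integer_, nd)

    step_gen <- function() {
      act <- which(colonized)
      # symmetric migration between demes adjacent in colonisation order
      if (cfg$migration_rate > 0 && length(act) > 1) {
        fn <- f
        for (d in act) {
          i <- match(d, ord)
          nb <- ord[c(i - 1, i + 1)]
          nb <- nb[!is.na(nb) & colonized[nb]]
          if (length(nb))
            fn[d, ] <- f[d, ] + cfg$migration_rate *
              colSums(matrix(f[nb, , drop = FALSE], ncol = nl) -
                        matrix(f[d, ], length(nb), nl, byrow = TRUE))
        }
        f <<- fn
      }
      for (d in act) {    # logistic growth then binomial drift
        N[d] <<- max(cfg$founder_size,
                     round(N[d] + cfg$growth_rate * N[d] * (1 - N[d] / cfg$carrying_capacity)))
        f[d, ] <<- stats::rbinom(nl, 2 * N[d], f[d, ]) / (2 * N[d])
      }
    }

    t <- 0L
    # ancestral deme at stationary frequencies, on the 2N allele-count
    # lattice of a finite population of size K
    K2 <- 2 * cfg$carrying_capacity
    f[ord[1], ] <- round(K2 * .draw_ancestral(cfg, nl)) / K2
    N[ord[1]] <- cfg$carrying_capacity
    colonized[ord[1]] <- TRUE
    col_time[ord[1]] <- t
    for (e in seq(2, nd)) {
      for (g in seq_len(cfg$gens_between)) { t <- t + 1L; step_gen() }
      src <- ord[e - 1]
      # founders are drawn without replacement from the source deme, so a
      # founding event with F = N_source copies the source exactly
      sz <- min(2 * cfg$founder_size, 2 * N[src])
      k_src <- round(2 * N[src] * f[src, ])
      f[ord[e], ] <- stats::rhyper(nl, k_src, 2 * N[src] - k_src, sz) / sz
      N[ord[e]] <- sz %/% 2L
      colonized[ord[e]] <- TRUE
      col_time[ord[e]] <- t
    }
    for (g in seq_len(cfg$gens_after)) { t <- t + 1L; step_gen() }

    # per-deme sampling through two internal patches whose divergence from
    # the deme mean decays with time since colonisation (Wahlund structure
    # at the invasion front)
    mats <- lapply(seq_len(nd), function(d) {
      n <- cfg$samples_per_deme[d]
      Fd <- cfg$wahlund_fst0 * exp(-(t - col_time[d]) / cfg$wahlund_tau)
      patch <- rep(1:2, length.out = n)
      if (Fd > 1e-6) {
        sh <- (1 - Fd) / Fd
        pf <- vapply(1:2, function(k) {
          seg <- f[d, ] > 0 & f[d, ] < 1
          out <- f[d, ]
          out[seg] <- stats::rbeta(sum(seg), f[d, seg] * sh, (1 - f[d, seg]) * sh)
          out
        }, numeric(nl))
      } else pf <- cbind(f[d, ], f[d, ])
      m <- matrix(NA_integer_, n, nl)
      for (k in 1:2) {
        rows <- which(patch == k)
        m[rows, ] <- stats::rbinom(length(rows) * nl, 2,
                                   rep(pf[, k], each = length(rows)))
      }
      if (cfg$missing_rate > 0)
        m[stats::runif(length(m)) < cfg$missing_rate] <- NA_integer_
      rownames(m) <- sprintf("%s_%02d", labels[d], seq_len(n))
      m
    })
    calls <- do.call(rbind, mats)
    pops_of_sample <- stats::setNames(
      rep(labels, cfg$samples_per_deme),
      rownames(calls))
    positions_km <- (match(seq_len(nd), ord) - 1) * cfg$deme_spacing_km
    truth <- structure(list(origin = labels[ord[1]],
                            colonization_order = labels[ord],
                            colonization_times = col_time,
                            positions_km = stats::setNames(positions_km, labels),
                            final_freqs = f,
                            config = cfg, seed = cfg$seed),
                       class = "sim_truth")
    .build_sim_output(calls, cfg, pops_of_sample, positions_km, truth)
  })
  out
}

#' Simulate an island-model null dataset at a target F_ST
#'
#' Balding-Nichols frequency draws around shared ancestral frequencies
#' (`target_fst = 0` gives identical deme frequencies), then binomial
#' diploid genotypes. Used to calibrate the outlier scans and the
#' regression/psi null behaviour.
#'
#' @param n_pops number of populations.
#' @param n_loci number of loci.
#' @param target_fst island-model F_ST (0 allowed).
#' @param samples_per_pop diploids per population (recycled).
#' @param missing_rate per-call missing probability.
#' @param seed integer seed.
#' @return list `gm`, `pm`, `truth` as in [simulate_expansion()] (truth
#'   records the target F_ST; no origin).
#' @export
simulate_null <- function(n_pops = 9, n_loci = 10000, target_fst = 0.01,
                          samples_per_pop = c(11, 9, 11, 14, 16, 7, 20, 15, 16),
                          missing_rate = 0.05, seed = 1L) {
  with_seed(seed, {
    labels <- sprintf("D%d", seq_len(n_pops))
    ns <- rep_len(samples_per_pop, n_pops)
    p0 <- stats::runif(n_loci, 0.05, 0.95)
    freqs <- lapply(seq_len(n_pops), function(d) {
      if (target_fst <= 0) p0
      else {
        sh <- (1 - target_fst) / target_fst
        stats::rbeta(n_loci, p0 * sh, (1 - p0) * sh)
      }
    })
    calls <- .sample_genotypes(freqs, ns, missing_rate, labels)
    pops_of_sample <- stats::setNames(rep(labels, ns), rownames(calls))
    positions_km <- (seq_len(n_pops) - 1) * 500
    truth <- structure(list(origin = NA_character_, target_fst = target_fst,
                            ancestral = p0, seed = seed),
                       class = "sim_truth")
    .build_sim_output(calls, NULL, pops_of_sample, positions_km, truth)
  })
}

#' Toy ocean grid for distance tests
#'
#' @param rows,cols grid dimensions.
#' @param land two-column matrix of (row, col) land-cell indices, or a
#'   logical matrix (`TRUE` = land), or `NULL`.
#' @param cell_km cell size.
#' @return ocean_grid (planar).
#' @export
make_toy_ocean_grid <- function(rows, cols, land = NULL, cell_km = 1) {
  water <- matrix(TRUE, rows, cols)
  if (!is.null(land)) {
    if (is.logical(land)) water[land] <- FALSE
    else water[as.matrix(land)] <- FALSE
  }
  if (!any(water)) .stopf("grid has no water cells")
  ocean_grid(water, cell_km = cell_km)
}

#' Simulate fish lengths from an age distribution
#'
#' Ages are drawn, standard lengths follow the forward von Bertalanffy
#' curve plus Gaussian noise, and total lengths invert the TL-to-SL
#' conversion.
#'
#' @param n number of fish.
#' @param params growth_params.
#' @param age_range uniform age range in years. The default stops at 5
#'   years: beyond that the growth curve is within a few mm of its
#'   asymptote and length carries almost no age information.
#' @param noise_sd Gaussian length noise, mm.
#' @param seed integer seed.
#' @return data.frame `age`, `sl_mm`, `tl_mm`.
#' @export
simulate_lengths <- function(n, params = growth_params(),
                             age_range = c(0.5, 5), noise_sd = 5, seed = 1L) {
  with_seed(seed, {
    age <- stats::runif(n, age_range[1], age_range[2])
    sl <- length_at_age(age, params) + stats::rnorm(n, 0, noise_sd)
    sl <- pmin(pmax(sl, 1), params$linf - 1e-6)
    tl <- (sl - params$tl_sl_intercept) / params$tl_sl_slope
    data.frame(age = age, sl_mm = sl, tl_mm = tl)
  })
}
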