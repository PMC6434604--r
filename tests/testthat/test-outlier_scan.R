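# F_ST-outlier scan (Balding-Nichols null) and environmental-association scan

test_that("Balding-Nichols draws have the stated moments and F -> 0 limit", {
  set.seed(6)
  p0 <- 0.3; F <- 0.05
  sh <- (1 - F) / F
  x <- rbeta(20000, p0 * sh, (1 - p0) * sh)
  expect_equal(mean(x), p0, tolerance = 0.01)
  expect_equal(var(x), p0 * (1 - p0) * F, tolerance = 0.001)
  # F -> 0: frequencies concentrate at the ancestral value, theta near 0
  nl <- simulate_null(n_pops = 4, n_loci = 300, target_fst = 0.0005,
                      samples_per_pop = 30, missing_rate = 0, seed = 9)
  eng <- edgefront:::.pop_locus_engine(nl$gm, nl$pm)
  th <- edgefront:::.theta_multilocus(
    edgefront:::.wc_components(eng$n_ind, eng$p_alt, eng$h_obs))
  expect_lt(abs(th), 0.01)
})

test_that("the envelope excludes roughly 1 - conf of fresh null loci", {
  nl <- simulate_null(n_pops = 9, n_loci = 10000, target_fst = 0.01, seed = 14)
  env <- suppressWarnings(build_null_envelope(nl$gm, nl$pm, target_fst = 0.01,
                                              n_sims = 30000, conf = 0.95, seed = 15))
  sc <- fst_outliers(nl$gm, nl$pm, env)
  poly <- sc$he > 0 & !is.na(sc$theta)
  # two-sided envelope at 0.95: ~2.5% above the upper bound
  frac_hi <- mean(sc$theta[poly] > sc$upper[poly])
  expect_gt(frac_hi, 0.005)
  expect_lt(frac_hi, 0.06)
})

test_that("monomorphic loci are never flagged and a planted outlier is", {
  nl <- simulate_null(n_pops = 9, n_loci = 3000, target_fst = 0.01,
                      missing_rate = 0, seed = 25)
  gm <- nl$gm
  # plant: extreme frequency cline across the nine populations
  rows <- edgefront:::.pop_rows(gm, nl$pm)
  planted <- unlist(lapply(seq_along(rows), function(k) {
    f <- c(0.02, 0.98)[(k %% 2) + 1]
    stats::rbinom(length(rows[[k]]), 2, f)
  }))
  gm$calls[unlist(rows), 1] <- as.integer(planted)
  gm$calls[, 2] <- 0L                      # monomorphic locus
  env <- suppressWarnings(build_null_envelope(gm, nl$pm, target_fst = 0.01,
                                              n_sims = 20000, seed = 26))
  sc <- fst_outliers(gm, nl$pm, env, fdr = 0.01)
  expect_true(sc$outlier[1])
  expect_false(sc$outlier[2])
  expect_true(is.na(sc$theta[2]) || !sc$outlier_envelope[2])
})

test_that("environmental scores hit the stated identity and degenerate cases", {
  # frequencies perfectly monotone in the gradient, identity covariance
  pops <- paste0("P", 1:6)
  calls <- do.call(rbind, lapply(1:6, function(k) {
    # deterministic dosages giving alt frequency k/10 at locus 1
    m <- matrix(0L, 10, 3)
    m[seq_len(k), 1] <- 2L
    m[, 2] <- 1L     # constant-frequency locus across pops
    m[, 3] <- 0L     # monomorphic locus
    rownames(m) <- sprintf("%s_%02d", pops[k], 1:10)
    m
  }))
  gm <- genotype_matrix(calls)
  pm <- population_map(stats::setNames(rep(pops, each = 10), rownames(calls)))
  grad <- stats::setNames(seq(0, 2500, length.out = 6), pops)
  sc <- env_assoc_scores(gm, pm, grad, covariance = "identity")
  expect_equal(sc$score[1], 1)
  expect_equal(sc$score[2], 0)   # constant across pops -> degenerate
  expect_equal(sc$score[3], 0)

  # permutation of the gradient leaves scores exchangeable on null data
  nl <- simulate_null(n_pops = 6, n_loci = 500, target_fst = 0.02,
                      samples_per_pop = 10, seed = 33)
  g0 <- stats::setNames(seq(0, 2500, length.out = 6), nl$pm$pops)
  s0 <- mean(env_assoc_scores(nl$gm, nl$pm, g0)$score)
  set.seed(34)
  sp <- vapply(1:20, function(i) {
    gp <- stats::setNames(sample(g0), names(g0))
    mean(env_assoc_scores(nl$gm, nl$pm, gp)$score)
  }, numeric(1))
  # observed mean score within the permutation spread
  expect_gt(mean(sp >= s0), 0.05)
})

test_that("empirical rank binning selects exactly the top fraction per bin", {
  # one crowded bin: 100 loci all at major frequency ~0.95 so p/q fall in
  # the first or last decimal bin; make scores distinct
  sc <- data.frame(locus_id = sprintf("L%03d", 1:100),
                   score = seq(1, 0.01, length.out = 100),
                   p_major = 0.55)   # p = 0.55 or q = 0.45: bins 6 and 5
  sel <- empirical_rank_bins(sc, top_frac = 0.05, seed = 41)
  d <- sel$detail
  for (b in unique(d$bin)) {
    db <- d[d$bin == b, ]
    n_sel <- sum(db$selected)
    expect_equal(n_sel, floor(0.05 * nrow(db)))
    # the selected ones are exactly the top scorers of the bin
    if (n_sel > 0)
      expect_true(min(db$score[db$selected]) >= max(db$score[!db$selected]))
  }

  # a bin of 10 loci can never satisfy q <= 0.05 (min quantile 0.1)
  sc2 <- data.frame(locus_id = sprintf("S%02d", 1:10),
                    score = runif(10), p_major = 1)   # frequency exactly 1.0
  sel2 <- suppressMessages(empirical_rank_bins(sc2, top_frac = 0.05, seed = 42))
  expect_length(sel2$selected, 0)
  expect_true(all(sel2$detail$bin %in% c(1L, 10L)))   # p/q coin flips at 1.0

  # identical seed -> identical coin flips and selection
  a <- empirical_rank_bins(sc, top_frac = 0.10, seed = 7)
  b <- empirical_rank_bins(sc, top_frac = 0.10, seed = 7)
  expect_identical(a, b)

  # selection invariant under monotone transform of scores
  sc3 <- sc; sc3$score <- exp(3 * sc3$score)
  expect_identical(empirical_rank_bins(sc, 0.05, seed = 11)$selected,
                   empirical_rank_bins(sc3, 0.05, seed = 11)$selected)
})

test_that("both scans overlap more than independent random selection would", {
  sim <- simulate_expansion(expansion_config(seed = 61, n_loci = 4000))
  env <- suppressWarnings(build_null_envelope(sim$gm, sim$pm, target_fst = 0.02,
                                              n_sims = 20000, seed = 62))
  fo <- fst_outliers(sim$gm, sim$pm, env, fdr = 0.05)
  set_f <- fo$locus_id[fo$outlier_envelope]      # envelope exceedances
  grad <- stats::setNames(sim$truth$positions_km[sim$pm$pops], sim$pm$pops)
  sc <- env_assoc_scores(sim$gm, sim$pm, grad)
  set_e <- empirical_rank_bins(sc, top_frac = 0.10, seed = 63)$selected
  n <- ncol(sim$gm$calls)
  k <- length(intersect(set_f, set_e))
  # one-sided hypergeometric enrichment test
  p <- stats::phyper(k - 1, length(set_f), n - length(set_f), length(set_e),
                     lower.tail = FALSE)
  expect_lt(p, 0.05)
})
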