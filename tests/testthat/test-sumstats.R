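# diversity statistics against enumeration oracles and pinned conventions

test_that("locus_pop_stats matches the worked toy and the formula edge cases", {
  fx <- toy_gm(list(A = matrix(c(0L, 0L, 1L, 2L), 4, 1)))
  s <- locus_pop_stats(fx$gm, fx$pm)
  expect_equal(s$p, 0.625)
  expect_equal(s$h_obs, 0.25)
  expect_equal(s$h_exp, 0.46875)
  expect_equal(s$pi, 0.5357143, tolerance = 1e-6)
  expect_equal(s$fis, 0.4666667, tolerance = 1e-6)

  # all heterozygous at p = 0.5 -> F_IS = -1
  fx2 <- toy_gm(list(A = matrix(1L, 4, 1)))
  s2 <- locus_pop_stats(fx2$gm, fx2$pm)
  expect_equal(s2$h_obs, 1)
  expect_equal(s2$h_exp, 0.5)
  expect_equal(s2$fis, -1)

  # monomorphic -> H_S = 0, F_IS undefined (NA), never 0
  fx3 <- toy_gm(list(A = matrix(0L, 4, 1)))
  s3 <- locus_pop_stats(fx3$gm, fx3$pm)
  expect_equal(s3$h_exp, 0)
  expect_true(is.na(s3$fis))
})

test_that("statistics equal the enumeration oracle on random small matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    calls <- matrix(sample(c(0:2, NA), 80, replace = TRUE,
                           prob = c(0.3, 0.3, 0.3, 0.1)), 8, 10)
    rownames(calls) <- sprintf("s%d", 1:8)
    gm <- genotype_matrix(calls)
    pm <- population_map(stats::setNames(rep(c("A", "B"), each = 4), rownames(calls)))
    st <- locus_pop_stats(gm, pm)
    for (i in seq_len(nrow(st))) {
      rows <- if (st$pop[i] == "A") 1:4 else 5:8
      o <- oracle_pop_stats(calls[rows, match(st$locus_id[i], gm$loci$locus_id)])
      if (o$n_ind == 0) { expect_equal(st$n[i], 0); next }
      expect_equal(st$p[i], o$p)
      expect_equal(st$h_obs[i], o$h_obs)
      expect_equal(st$h_exp[i], o$h_exp)
      expect_equal(st$pi[i], o$pi)
      expect_equal(st$fis[i], o$fis)
    }
  }
})

test_that("rarefied richness matches hypergeometric closed form and enumeration", {
  expect_equal(rarefied_richness(c(6, 2), 4), 1 + (1 - 15 / 70), tolerance = 1e-9)
  expect_equal(rarefied_richness(c(6, 2), 4), oracle_rarefaction(c(6, 2), 4),
               tolerance = 1e-9)
  expect_equal(rarefied_richness(c(5, 3, 2), 4), oracle_rarefaction(c(5, 3, 2), 4),
               tolerance = 1e-9)
  expect_equal(rarefied_richness(c(8), 3), 1.0)          # monomorphic
  expect_equal(rarefied_richness(c(6, 2), 8), 2)         # g = N: observed count
  expect_error(rarefied_richness(c(6, 2), 9), "gene copies")
})

test_that("private alleles and population summaries behave as specified", {
  # pop A uniquely carries alt at locus 1; locus 2 monomorphic shared
  fx <- toy_gm(list(A = rbind(c(1L, 0L), c(0L, 0L)),
                    B = rbind(c(0L, 0L), c(0L, 0L))))
  sa <- population_summary(fx$gm, fx$pm, "A")
  sb <- population_summary(fx$gm, fx$pm, "B")
  expect_equal(sa$private, 1L)
  expect_equal(sb$private, 0L)

  # two identical monomorphic pops -> no private alleles anywhere
  fx2 <- toy_gm(list(A = matrix(0L, 3, 2), B = matrix(0L, 3, 2)))
  expect_equal(population_summary(fx2$gm, fx2$pm, "A")$private, 0L)
  expect_equal(population_summary(fx2$gm, fx2$pm, "B")$private, 0L)

  # means equal hand-averaged per-locus oracle values on a toy matrix
  set.seed(42)
  calls <- matrix(sample(0:2, 30, replace = TRUE), 10, 3)
  rownames(calls) <- sprintf("s%d", 1:10)
  gm <- genotype_matrix(calls)
  pm <- population_map(stats::setNames(rep(c("A", "B"), each = 5), rownames(calls)))
  sm <- population_summary(gm, pm, "A")
  oc <- lapply(1:3, function(j) oracle_pop_stats(calls[1:5, j]))
  expect_equal(sm$obs_het_mean, mean(vapply(oc, `[[`, numeric(1), "h_obs")))
  expect_equal(sm$exp_het_mean, mean(vapply(oc, `[[`, numeric(1), "h_exp")))
  expect_equal(sm$pi_mean, mean(vapply(oc, `[[`, numeric(1), "pi")))
  fis_vals <- vapply(oc, `[[`, numeric(1), "fis")
  expect_equal(sm$fis_mean, mean(fis_vals[!is.na(fis_vals)]))
})

test_that("F_IS distribution drops undefined records and bins on [-1,1]", {
  d <- fis_distribution(c(-0.5, 0.1, 0.9, 0.9, NA, NA))
  expect_equal(sum(d$proportion), 1)
  expect_equal(d$proportion[d$bin_left == -0.6], 0.25)
  expect_equal(d$proportion[d$bin_left == 0.0], 0.25)
  expect_equal(d$proportion[d$bin_left == 0.8], 0.5)   # 1.0 closes the last bin
  expect_false(attr(d, "empty"))

  expect_warning(e <- fis_distribution(c(NA_real_, NA_real_)), "undefined")
  expect_true(attr(e, "empty"))

  # exclusion is a pure filter: defined records unchanged by dropping NA
  v <- c(-0.9, -0.1, 0.2, 0.7)
  expect_equal(fis_distribution(c(v, NA))$proportion, fis_distribution(v)$proportion)
})

test_that("SFS binning: fixed loci in terminal bin, distinct bins, mirror fold", {
  fx <- toy_gm(list(A = rbind(c(0L, 1L, 2L), c(0L, 0L, 2L),
                              c(0L, 0L, 2L), c(0L, 0L, 2L), c(0L, NA, 2L))))
  # major-allele freqs per locus: 1.0, 0.875, 1.0 (off bin edges so the
  # folded spectrum mirrors exactly)
  d <- folded_sfs(fx$gm, fx$pm, "A", n_bins = 10)
  expect_equal(sum(d$proportion), 1)
  expect_equal(d$proportion[10], 2 / 3)            # two fixed loci, last bin
  f <- folded_sfs(fx$gm, fx$pm, "A", n_bins = 10, folded = TRUE)
  expect_equal(rev(f$proportion), d$proportion)    # mirrored spectrum

  # frequencies {0.55, 0.95}: mass 0.5 in two distinct bins
  fx2 <- toy_gm(list(A = rbind(c(1L, 0L), c(1L, 0L), c(1L, 0L), c(1L, 0L),
                               c(1L, 0L), c(1L, 0L), c(1L, 0L), c(1L, 0L),
                               c(1L, 0L), c(2L, 1L))))
  d2 <- folded_sfs(fx2$gm, fx2$pm, "A", n_bins = 10)
  expect_equal(sort(d2$proportion[d2$proportion > 0]), c(0.5, 0.5))
  expect_equal(sum(d2$proportion > 0), 2)
})

test_that("mean expected heterozygosity is non-negative and F_IS sign follows H_S - H_I", {
  sim <- simulate_expansion(expansion_config(seed = 8, n_loci = 300))
  st <- locus_pop_stats(sim$gm, sim$pm)
  ok <- !is.na(st$fis)
  expect_true(all(st$h_exp >= 0, na.rm = TRUE))
  expect_true(all(sign(st$fis[ok]) == sign(st$h_exp[ok] - st$h_obs[ok])))
})
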