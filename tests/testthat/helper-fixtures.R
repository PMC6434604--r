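# Fixtures are built in code; independent brute-force oracles live here so
# tests never validate an implementation against itself.

# small genotype matrix with explicit dosages; one population per group
toy_gm <- function(dosages_by_pop, loci = NULL) {
  calls <- do.call(rbind, dosages_by_pop)
  n_by <- vapply(dosages_by_pop, nrow, integer(1))
  labs <- names(dosages_by_pop)
  samples <- sprintf("%s_%02d", rep(labs, n_by), unlist(lapply(n_by, seq_len)))
  rownames(calls) <- samples
  gm <- genotype_matrix(calls, loci, samples)
  pm <- population_map(stats::setNames(rep(labs, n_by), samples))
  list(gm = gm, pm = pm)
}

# enumeration oracle for per-locus per-population statistics: straight
# loops over genotypes, no shared code with the package internals
oracle_pop_stats <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  n_ind <- length(d)
  n <- 2 * n_ind
  n_ref <- sum(2 - d)
  p <- n_ref / n
  q <- 1 - p
  h_obs <- sum(d == 1) / n_ind
  h_exp <- 2 * p * q
  pi <- if (n > 1) (n / (n - 1)) * (1 - p^2 - q^2) else NA_real_
  fis <- if (h_exp > 0) (h_exp - h_obs) / h_exp else NA_real_
  list(n_ind = n_ind, n = n, p = p, q = q, h_obs = h_obs, h_exp = h_exp,
       pi = pi, fis = fis)
}

# rarefaction oracle: exhaustive enumeration of all g-subsets of gene copies
oracle_rarefaction <- function(allele_counts, g) {
  pool <- rep(seq_along(allele_counts), allele_counts)
  subsets <- utils::combn(length(pool), g)
  mean(apply(subsets, 2, function(ix) length(unique(pool[ix]))))
}

# brute-force least-cost oracle: enumerate all simple paths on a tiny grid
oracle_shortest_path <- function(grid, src_cell, dst_cell) {
  nr <- nrow(grid$water); nc <- ncol(grid$water)
  nbrs <- function(cell) {
    r <- (cell - 1) %% nr + 1; c <- (cell - 1) %/% nr + 1
    out <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && grid$water[r2, c2])
        out <- c(out, (c2 - 1) * nr + r2)
    }
    out
  }
  dist2 <- function(a, b) sqrt((grid$x[a] - grid$x[b])^2 + (grid$y[a] - grid$y[b])^2)
  best <- Inf
  walk <- function(cell, visited, acc) {
    if (acc >= best) return(invisible())
    if (cell == dst_cell) { best <<- acc; return(invisible()) }
    for (nb in nbrs(cell)) if (!(nb %in% visited))
      walk(nb, c(visited, nb), acc + dist2(cell, nb))
  }
  walk(src_cell, src_cell, 0)
  best
}

# closed-form OLS oracle
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fit <- intercept + slope * x
  sse <- sum((y - fit)^2)
  sst <- sum((y - mean(y))^2)
  se <- sqrt(sse / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept, r_squared = 1 - sse / sst,
       p_value = 2 * stats::pt(-abs(t), n - 2))
}

# default small expansion used by several stochastic tests
small_expansion <- function(seed, n_loci = 4000) {
  simulate_expansion(expansion_config(seed = seed, n_loci = n_loci))
}
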