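# Weir & Cockerham (1984) theta from per-population allele frequencies,
# observed heterozygote fractions and sample sizes. Operates on
# population x locus matrices; returns per-locus variance components.
.wc_components <- function(n_ind, p, h) {
  use <- !is.na(p) & n_ind > 0
  r <- colSums(use)
  nm <- n_ind; nm[!use] <- 0
  pm <- p; pm[!use] <- 0
  hm <- h; hm[!use] <- 0
  sn <- colSums(nm)
  nbar <- sn / r
  nc <- (sn - colSums(nm^2) / sn) / (r - 1)
  pbar <- colSums(nm * pm) / sn
  s2 <- colSums(nm * (pm - pbar[col(pm)])^2) / ((r - 1) * nbar)
  hbar <- colSums(nm * hm) / sn
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1 | !is.finite(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(a = a, b = b, c = cc, r = r)
}

# multilocus theta = sum(a) / sum(a+b+c) over informative loci
.theta_multilocus <- function(comp) {
  ok <- !is.na(comp$a)
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  sum(comp$a[ok]) / denom
}

#' Pairwise Weir-Cockerham F_ST with permutation test
#'
#' Multilocus theta = sum(a) / sum(a + b + c) over loci genotyped in both
#' populations. Significance by permutation of individuals between the two
#' populations: p = (1 + #\{theta* >= theta\}) / (n_perm + 1).
#'
#' @param gm genotype_matrix.
#' @param pm population_map.
#' @param popA,popB population labels.
#' @param n_perm number of label permutations (0 = no test, p `NA`).
#' @param seed integer seed for the permutations.
#' @return object of class `fst_result`: list with `pops`, `theta`, `sum_a`,
#'   `sum_b`, `sum_c`, `n_loci`, `p_value`, `n_perm`, and `components`
#'   (per-locus data.frame).
#' @export
pairwise_fst <- function(gm, pm, popA, popB, n_perm = 0, seed = 1L) {
  rows <- .pop_rows(gm, pm)
  if (!all(c(popA, popB) %in% names(rows))) .stopf("unknown population")
  ia <- rows[[popA]]; ib <- rows[[popB]]
  if (length(ia) < 2 || length(ib) < 2)
    .stopf("both populations need >= 2 individuals")
  calls <- gm$calls[c(ia, ib), , drop = FALSE]
  grp <- rep(c(popA, popB), c(length(ia), length(ib)))

  stat_of <- function(g) {
    ni <- rbind(colSums(!is.na(calls[g == popA, , drop = FALSE])),
                colSums(!is.na(calls[g == popB, , drop = FALSE])))
    tot <- rbind(colSums(calls[g == popA, , drop = FALSE], na.rm = TRUE),
                 colSums(calls[g == popB, , drop = FALSE], na.rm = TRUE))
    het <- rbind(colSums(calls[g == popA, , drop = FALSE] == 1L, na.rm = TRUE),
                 colSums(calls[g == popB, , drop = FALSE] == 1L, na.rm = TRUE))
    p <- ifelse(ni > 0, tot / (2 * ni), NA_real_)
    h <- ifelse(ni > 0, het / ni, NA_real_)
    .wc_components(ni, p, h)
  }
  comp <- stat_of(grp)
  theta <- .theta_multilocus(comp)
  if (is.na(theta)) {
    .warnf("no shared polymorphic loci between %s and %s; theta set to 0", popA, popB)
    theta <- 0
  }
  p_value <- NA_real_
  if (n_perm > 0) {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(k) {
        th <- .theta_multilocus(stat_of(sample(grp)))
        !is.na(th) && th >= theta
      }, logical(1)))
    })
    p_value <- (1 + exceed) / (n_perm + 1)
  }
  ok <- !is.na(comp$a)
  structure(list(pops = c(popA, popB), theta = theta,
                 sum_a = sum(comp$a[ok]), sum_b = sum(comp$b[ok]),
                 sum_c = sum(comp$c[ok]), n_loci = sum(ok),
                 p_value = p_value, n_perm = n_perm,
                 components = data.frame(locus_id = gm$loci$locus_id,
                                         a = comp$a, b = comp$b, c = comp$c)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("F_ST (WC84) %s vs %s: theta = %.5g over %d loci",
              x$pops[1], x$pops[2], x$theta, x$n_loci))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g (%d perms)", x$p_value, x$n_perm))
  cat("\n")
  invisible(x)
}

#' All pairwise F_ST values with Bonferroni-corrected significance
#'
#' @param gm genotype_matrix.
#' @param pm population_map.
#' @param n_perm permutations per pair.
#' @param alpha nominal significance level; pairs are significant when
#'   `p <= alpha / n_pairs`.
#' @param seed base seed (each pair uses a derived sub-seed).
#' @return list with symmetric matrices `theta`, `p_value`, `significant`,
#'   plus `n_pairs`, `alpha`, `bonferroni_alpha`.
#' @export
fst_matrix <- function(gm, pm, n_perm = 100, alpha = 0.05, seed = 1L) {
  pops <- pm$pops
  k <- length(pops)
  n_pairs <- k * (k - 1) / 2
  th <- matrix(0, k, k, dimnames = list(pops, pops))
  pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  idx <- 0
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    idx <- idx + 1
    r <- pairwise_fst(gm, pm, pops[i], pops[j], n_perm = n_perm,
                      seed = .sub_seed(seed, idx))
    th[i, j] <- th[j, i] <- r$theta
    pv[i, j] <- pv[j, i] <- r$p_value
  }
  sig <- !is.na(pv) & pv <= alpha / n_pairs
  list(theta = th, p_value = pv, significant = sig,
       n_pairs = n_pairs, alpha = alpha, bonferroni_alpha = alpha / n_pairs)
}
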