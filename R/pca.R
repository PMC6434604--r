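#' PCA of genetic diversity with iterative outlier removal
#'
#' smartpca-style analysis: dosages are mean-centered and scaled by
#' `sqrt(p(1-p))` with `p` the allele frequency estimate from the column
#' mean; missing calls are imputed to the column mean; eigen-decomposition
#' of the sample covariance matrix. In each outlier iteration, samples lying
#' more than `sd_threshold` standard deviations from the mean on any of the
#' top `n_axes` axes are removed and the PCA recomputed. Equivalence with
#' smartpca is approximate (normalisation and the 6-SD rule follow the
#' EIGENSOFT description; exact numerics are not targeted).
#'
#' @param gm genotype_matrix.
#' @param n_axes number of axes to report (and to screen for outliers).
#' @param n_outlier_iters outlier-removal iterations (0 = none).
#' @param sd_threshold removal threshold in per-axis standard deviations.
#' @return object of class `pca_result`: `coords` (retained samples x
#'   `n_axes`), `percent_variance` (per reported axis), `eigenvalues` (all),
#'   `removed` (list of sample IDs removed per iteration), `samples`.
#' @export
pca <- function(gm, n_axes = 10, n_outlier_iters = 4, sd_threshold = 6) {
  if (nrow(gm$calls) < 3) .stopf("PCA needs >= 3 samples")
  keep <- gm$samples
  removed <- list()
  res <- NULL
  for (it in seq_len(n_outlier_iters + 1)) {
    X <- gm$calls[keep, , drop = FALSE]
    storage.mode(X) <- "double"
    cm <- colMeans(X, na.rm = TRUE)
    nax <- min(n_axes, length(keep) - 1)
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j]); if (any(nas)) X[nas, j] <- cm[j]
    }
    p <- cm / 2
    sdv <- sqrt(p * (1 - p))
    poly <- !is.na(sdv) & sdv > 0 & apply(X, 2, stats::var) > 0
    if (!any(poly)) .stopf("degenerate input: no polymorphic loci")
    Z <- sweep(X[, poly, drop = FALSE], 2, cm[poly])
    Z <- sweep(Z, 2, sdv[poly], "/")
    C <- tcrossprod(Z) / sum(poly)
    eg <- eigen(C, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    coords <- eg$vectors[, seq_len(nax), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(nax)]), nax)
    rownames(coords) <- keep
    colnames(coords) <- paste0("PC", seq_len(nax))
    res <- list(coords = coords,
                percent_variance = 100 * ev[seq_len(nax)] / sum(ev),
                eigenvalues = ev, removed = removed, samples = keep)
    if (it > n_outlier_iters) break
    z <- scale(coords)
    out <- rowSums(abs(z) > sd_threshold, na.rm = TRUE) > 0
    if (!any(out)) { res$removed <- removed; break }
    removed <- c(removed, list(keep[out]))
    keep <- keep[!out]
    if (length(keep) < 3) .stopf("outlier removal left fewer than 3 samples")
  }
  res$removed <- removed
  class(res) <- "pca_result"
  res
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d axes; removed %d outlier(s)\n",
              length(x$samples), ncol(x$coords), length(unlist(x$removed))))
  cat("percent variance:", paste(sprintf("%.2f", x$percent_variance), collapse = " "), "\n")
  invisible(x)
}
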