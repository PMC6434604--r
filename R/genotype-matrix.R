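#' Genotype matrix of biallelic SNP calls
#'
#' The central container of the package: an individuals-by-loci table of
#' alternate-allele dosages (0, 1, 2, or `NA` for missing) plus per-locus
#' metadata. All allele-level statistics are computed from dosages assuming
#' diploidy.
#'
#' @param calls integer matrix, samples in rows, loci in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param loci data.frame with columns `locus_id`, `tag_id` (RAD tag of
#'   origin), `pos` (position within the tag), `ref`, `alt`. If `NULL`, a
#'   minimal frame is synthesised (one tag per locus).
#' @param samples character vector of sample IDs; defaults to
#'   `rownames(calls)`.
#' @return an object of class `genotype_matrix` with elements `calls`,
#'   `samples`, `loci`.
#' @export
genotype_matrix <- function(calls, loci = NULL, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(nrow(calls)))
  if (is.null(loci)) {
    ids <- colnames(calls)
    if (is.null(ids)) ids <- sprintf("L%05d", seq_len(ncol(calls)))
    loci <- data.frame(locus_id = ids, tag_id = ids, pos = 1L,
                       ref = "A", alt = "C", stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  need <- c("locus_id", "tag_id", "pos", "ref", "alt")
  if (!all(need %in% names(loci)))
    .stopf("loci must have columns %s", paste(need, collapse = ", "))
  if (nrow(loci) != ncol(calls))
    .stopf("loci rows (%d) must match call columns (%d)", nrow(loci), ncol(calls))
  if (length(samples) != nrow(calls))
    .stopf("samples length must match call rows")
  if (anyDuplicated(paste(loci$tag_id, loci$pos)))
    .stopf("(tag_id, pos) pairs must be unique")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    .stopf("calls must be alt-allele dosages in {0,1,2} or NA")
  rownames(calls) <- samples
  colnames(calls) <- loci$locus_id
  structure(list(calls = calls, samples = as.character(samples), loci = loci),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d biallelic loci (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Subset a genotype matrix by loci and/or samples
#' @param gm genotype_matrix.
#' @param loci logical/integer/character index into loci.
#' @param samples logical/integer/character index into samples.
#' @return genotype_matrix.
#' @export
gm_subset <- function(gm, loci = NULL, samples = NULL) {
  calls <- gm$calls
  ltab <- gm$loci
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, ltab$locus_id)
    calls <- calls[, loci, drop = FALSE]
    ltab <- ltab[loci, , drop = FALSE]
    rownames(ltab) <- NULL
  }
  smp <- gm$samples
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, smp)
    calls <- calls[samples, , drop = FALSE]
    smp <- smp[samples]
  }
  genotype_matrix(calls, ltab, smp)
}

#' Population map: sample-to-site assignment with optional coordinates
#'
#' @param pop named character vector mapping sample ID to population label.
#' @param coords optional data.frame with columns `pop`, `lat`, `lon`
#'   (decimal degrees).
#' @return object of class `population_map` with elements `pop`, `pops`
#'   (sorted unique labels), `coords`.
#' @export
population_map <- function(pop, coords = NULL) {
  if (is.null(names(pop)) || anyDuplicated(names(pop)))
    .stopf("pop must be a named vector with unique sample names")
  pops <- sort(unique(unname(pop)))
  if (!is.null(coords)) {
    coords <- as.data.frame(coords, stringsAsFactors = FALSE)
    if (!all(c("pop", "lat", "lon") %in% names(coords)))
      .stopf("coords needs columns pop, lat, lon")
  }
  structure(list(pop = pop, pops = pops, coords = coords),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat(sprintf("population_map: %d samples in %d populations (%s)\n",
              length(x$pop), length(x$pops), paste(x$pops, collapse = ", ")))
  invisible(x)
}

#' Read a population map TSV
#'
#' Format: `sample<TAB>population[<TAB>lat<TAB>lon]`, no header.
#'
#' @param path file path.
#' @return population_map.
#' @export
read_popmap <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tb) < 2) .stopf("popmap needs at least 2 tab-separated columns")
  if (anyDuplicated(tb[[1]]))
    .stopf("duplicate sample in popmap: %s",
           paste(unique(tb[[1]][duplicated(tb[[1]])]), collapse = ", "))
  pop <- stats::setNames(as.character(tb[[2]]), tb[[1]])
  coords <- NULL
  if (ncol(tb) >= 4) {
    coords <- unique(data.frame(pop = tb[[2]], lat = as.numeric(tb[[3]]),
                                lon = as.numeric(tb[[4]]),
                                stringsAsFactors = FALSE))
    rownames(coords) <- NULL
  }
  population_map(pop, coords)
}

#' Write a population map TSV
#' @param pm population_map.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  df <- data.frame(sample = names(pm$pop), pop = unname(pm$pop))
  if (!is.null(pm$coords)) {
    i <- match(df$pop, pm$coords$pop)
    df$lat <- pm$coords$lat[i]
    df$lon <- pm$coords$lon[i]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Check genotype/popmap consistency
#'
#' @param gm genotype_matrix.
#' @param pm population_map.
#' @param strict if `TRUE` (default) error when the map lists samples absent
#'   from the genotype data; otherwise warn. Samples in `gm` missing from the
#'   map are always an error.
#' @return invisibly `TRUE`.
#' @export
check_popmap <- function(gm, pm, strict = TRUE) {
  unmapped <- setdiff(gm$samples, names(pm$pop))
  if (length(unmapped))
    .stopf("samples missing from popmap: %s", paste(unmapped, collapse = ", "))
  extra <- setdiff(names(pm$pop), gm$samples)
  if (length(extra)) {
    msg <- sprintf("popmap lists samples absent from genotype data: %s",
                   paste(extra, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(TRUE)
}

# list of sample-row indices per population, restricted to mapped samples
.pop_rows <- function(gm, pm) {
  check_popmap(gm, pm, strict = FALSE) |> suppressWarnings()
  lab <- pm$pop[gm$samples]
  lapply(stats::setNames(nm = pm$pops), function(p) which(lab == p))
}
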