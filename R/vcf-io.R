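#' Read biallelic SNPs from a VCF into a genotype matrix
#'
#' Uses Bioconductor's VariantAnnotation parser. Records that are not
#' biallelic SNPs (multiallelic ALT, or REF/ALT longer than one base) are
#' skipped and the skip count reported via `message()`. Genotypes `./.` (or
#' any GT containing `.`) become missing.
#'
#' @param path path to a VCF (v4.x) file with GT fields.
#' @return genotype_matrix. The skip count is attached as
#'   `attr(, "n_skipped")`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) .stopf("cannot read VCF: %s", path)
  vcf <- VariantAnnotation::readVcf(path)
  n <- nrow(vcf)
  if (n == 0L) .stopf("VCF contains no records: %s", path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt1 <- vapply(seq_len(n), function(i) {
    a <- altl[[i]]
    if (length(a) == 1L) as.character(a) else ""
  }, character(1))
  keep <- nchar(ref) == 1L & nchar(alt1) == 1L & alt1 != ""
  n_skip <- sum(!keep)
  if (!any(keep)) .stopf("no biallelic SNP records in %s", path)
  if (n_skip > 0)
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)", n_skip))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) .stopf("VCF has no GT field: %s", path)
  gt <- gt[keep, , drop = FALSE]
  rr <- SummarizedExperiment::rowRanges(vcf)[keep]
  ids <- names(rr)
  if (is.null(ids)) ids <- sprintf("L%05d", seq_len(sum(keep)))
  loci <- data.frame(
    locus_id = ids,
    tag_id = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = ref[keep], alt = alt1[keep],
    stringsAsFactors = FALSE)
  # GT string -> alt dosage; any '.' allele -> NA
  u <- unique(as.vector(gt))
  dos_of <- vapply(u, function(g) {
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".") || length(al) == 0L) return(NA_integer_)
    sum(al == "1")
  }, integer(1))
  calls <- matrix(dos_of[match(as.vector(gt), u)], nrow = nrow(gt))
  calls <- t(calls)   # loci x samples -> samples x loci
  gm <- genotype_matrix(calls, loci, samples = colnames(gt))
  attr(gm, "n_skipped") <- n_skip
  gm
}

#' Write a genotype matrix to a VCF file
#'
#' Plain-text VCF v4.2 writer (GT-only). Loci are written with
#' `CHROM = tag_id`, `POS = pos`, `ID = locus_id`.
#'
#' @param gm genotype_matrix.
#' @param path output path.
#' @param meta optional named list recorded as `##edgefront_<key>=` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (k in names(meta))
    writeLines(sprintf("##edgefront_%s=%s", k, paste(meta[[k]], collapse = ",")), con)
  for (tg in unique(gm$loci$tag_id))
    writeLines(sprintf("##contig=<ID=%s>", tg), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)
  gtcode <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(gm$calls))) {
    d <- gm$calls[, j]
    gt <- ifelse(is.na(d), "./.", gtcode[d + 1L])
    l <- gm$loci[j, ]
    writeLines(paste(c(l$tag_id, l$pos, l$locus_id, l$ref, l$alt, ".", ".",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Export genotypes in STRUCTURE format
#'
#' Two rows per individual (one allele per row), alleles coded 1 (ref) and
#' 2 (alt), missing as -9. First two columns: sample ID, population label.
#'
#' @param gm genotype_matrix.
#' @param pm population_map.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(gm, pm, path) {
  check_popmap(gm, pm, strict = FALSE) |> suppressWarnings()
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(gm$samples)) {
    d <- gm$calls[i, ]
    a1 <- ifelse(is.na(d), -9L, ifelse(d >= 1L, 2L, 1L))
    a2 <- ifelse(is.na(d), -9L, ifelse(d == 2L, 2L, 1L))
    pre <- c(gm$samples[i], unname(pm$pop[gm$samples[i]]))
    writeLines(paste(c(pre, a1), collapse = "\t"), con)
    writeLines(paste(c(pre, a2), collapse = "\t"), con)
  }
  invisible(path)
}
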