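# genotype container, VCF/popmap IO, and the -p/-r retention filters

write_test_vcf <- function(path, records, samples = c("s1", "s2")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
}

test_that("read_vcf parses biallelic SNPs, missing calls, and skips multiallelics", {
  p <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(p, c(
    "t1\t5\tL1\tA\tC\t.\t.\t.\tGT\t0/0\t0/1",
    "t1\t9\tL2\tG\tT\t.\t.\t.\tGT\t1/1\t./.",
    "t2\t5\tL3\tA\tC,G\t.\t.\t.\tGT\t0/1\t0/2",   # multiallelic -> skipped
    "t3\t5\tL4\tA\tC\t.\t.\t.\tGT\t0|1\t1|1",
    "t4\t5\tL5\tAT\tA\t.\t.\t.\tGT\t0/0\t0/1"))   # indel -> skipped
  expect_message(gm <- read_vcf(p), "skipped 2")
  expect_equal(dim(gm), c(2L, 3L))
  expect_equal(attr(gm, "n_skipped"), 2L)
  expect_equal(unname(gm$calls[, "L1"]), c(0L, 1L))
  expect_true(is.na(gm$calls["s2", "L2"]))
  expect_equal(unname(gm$calls[, "L4"]), c(1L, 2L))  # phased parsed too
  expect_equal(gm$loci$tag_id, c("t1", "t1", "t3"))
})

test_that("read_vcf errors on unreadable input and on zero biallelic records", {
  expect_error(read_vcf(file.path(tempdir(), "nope.vcf")), "cannot read")
  p <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(p, "t1\t5\tL1\tA\tC,G\t.\t.\t.\tGT\t0/1\t0/2")
  expect_error(suppressMessages(read_vcf(p)), "no biallelic")
})

test_that("VCF round-trip preserves calls, loci and samples exactly", {
  sim <- simulate_expansion(expansion_config(seed = 11, n_loci = 200,
                                             samples_per_deme = 6))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$gm, p)
  gm2 <- read_vcf(p)
  expect_identical(unname(gm2$calls), unname(sim$gm$calls))
  expect_identical(gm2$loci$locus_id, sim$gm$loci$locus_id)
  expect_identical(gm2$samples, sim$gm$samples)
})

test_that("popmap reading validates duplicates and cross-checks samples", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tA\t25.5\t-80.2", "s2\tA\t25.5\t-80.2",
               "s3\tB\t18.3\t-64.8", "s4\tB\t18.3\t-64.8"), p)
  pm <- read_popmap(p)
  expect_length(pm$pop, 4)
  expect_equal(pm$pops, c("A", "B"))
  expect_equal(nrow(pm$coords), 2)

  writeLines(c("s1\tA", "s1\tB"), p)
  expect_error(read_popmap(p), "duplicate")

  gm <- genotype_matrix(matrix(0L, 2, 1), samples = c("s1", "s2"))
  pm2 <- population_map(c(s1 = "A", s2 = "A", s9 = "B"))
  expect_error(check_popmap(gm, pm2, strict = TRUE), "absent")
  expect_warning(check_popmap(gm, pm2, strict = FALSE), "absent")
})

test_that("structure export writes two rows per individual with -9 missing", {
  fx <- toy_gm(list(A = rbind(c(0L, 1L), c(2L, NA))))
  p <- withr::local_tempfile(fileext = ".str")
  write_structure(fx$gm, fx$pm, p)
  lines <- readLines(p)
  expect_length(lines, 4)
  # sample 1 dosages (0, 1): allele rows (1,2) then (1,1)
  expect_equal(strsplit(lines[1], "\t")[[1]][3:4], c("1", "2"))
  expect_equal(strsplit(lines[2], "\t")[[1]][3:4], c("1", "1"))
  # sample 2 dosages (2, NA): second allele row (2, -9)
  expect_equal(strsplit(lines[4], "\t")[[1]][3:4], c("2", "-9"))
})

make_filter_fixture <- function() {
  # 3 pops x 5 individuals; loci engineered against the -p/-r boundaries
  calls <- matrix(0L, 15, 4)
  colnames(calls) <- c("La", "Lb", "Lc", "Ld")
  # La: genotyped everywhere
  # Lb: pop3 fully missing -> present in 2 pops only
  calls[11:15, 2] <- NA
  # Lc: pop1 has exactly 4/5 genotyped (0.8 boundary)
  calls[1, 3] <- NA
  # Ld: pop1 has 3/5 genotyped (0.6 < 0.8)
  calls[1:2, 4] <- NA
  samples <- sprintf("s%02d", 1:15)
  rownames(calls) <- samples
  gm <- genotype_matrix(calls, samples = samples)
  pm <- population_map(stats::setNames(rep(c("P1", "P2", "P3"), each = 5), samples))
  list(gm = gm, pm = pm)
}

test_that("-p/-r retention implements inclusive boundaries and Stacks presence", {
  fx <- make_filter_fixture()
  keep3 <- apply_locus_filters(fx$gm, fx$pm,
    filter_config(min_populations = 3, min_fraction_individuals = 0.8,
                  one_snp_per_tag = FALSE))
  # Lb out (2 pops), Ld out (pop1 below 0.8); Lc in (0.8 inclusive)
  expect_equal(keep3$loci$locus_id, c("La", "Lc"))
  # at -p 2 even Lb (2 pops) and Ld (below 0.8 only in pop1) survive
  keep2 <- apply_locus_filters(fx$gm, fx$pm,
    filter_config(min_populations = 2, min_fraction_individuals = 0.8,
                  one_snp_per_tag = FALSE))
  expect_equal(keep2$loci$locus_id, c("La", "Lb", "Lc", "Ld"))
  # loci that are nowhere fully genotyped all fail -r 0.95 at -p 3
  gm_part <- gm_subset(fx$gm, loci = c("Lc", "Ld"))
  expect_error(apply_locus_filters(gm_part, fx$pm,
    filter_config(min_populations = 3, min_fraction_individuals = 0.95,
                  one_snp_per_tag = FALSE)), "no loci")
})

test_that("filtering is idempotent and monotone in both thresholds", {
  sim <- simulate_expansion(expansion_config(seed = 3, n_loci = 500,
                                             missing_rate = 0.25))
  cfg <- filter_config(min_populations = 7, min_fraction_individuals = 0.7,
                       one_snp_per_tag = FALSE)
  f1 <- apply_locus_filters(sim$gm, sim$pm, cfg)
  f2 <- apply_locus_filters(f1, sim$pm, cfg)
  expect_identical(f1$loci$locus_id, f2$loci$locus_id)

  n_kept <- function(p, r) ncol(apply_locus_filters(sim$gm, sim$pm,
    filter_config(p, r, one_snp_per_tag = FALSE))$calls)
  counts_p <- vapply(5:9, n_kept, numeric(1), r = 0.7)
  expect_true(all(diff(counts_p) <= 0))
  counts_r <- vapply(c(0.5, 0.6, 0.7, 0.8), function(r) n_kept(7, r), numeric(1))
  expect_true(all(diff(counts_r) <= 0))
})

test_that("one SNP per tag is seeded, reproducible, and keeps one per tag", {
  calls <- matrix(sample(0:2, 60, replace = TRUE), 5, 12)
  loci <- data.frame(locus_id = sprintf("L%02d", 1:12),
                     tag_id = rep(c("t1", "t2", "t3"), each = 4),
                     pos = rep(1:4, 3), ref = "A", alt = "C")
  samples <- paste0("s", 1:5)
  rownames(calls) <- samples
  gm <- genotype_matrix(calls, loci, samples)
  pm <- population_map(stats::setNames(rep("A", 5), samples))
  cfg <- filter_config(min_populations = 1, min_fraction_individuals = 0.5,
                       one_snp_per_tag = TRUE, seed = 99)
  a <- apply_locus_filters(gm, pm, cfg)
  b <- apply_locus_filters(gm, pm, cfg)
  expect_equal(ncol(a$calls), 3)
  expect_identical(a$loci$locus_id, b$loci$locus_id)
  expect_equal(sort(unique(a$loci$tag_id)), c("t1", "t2", "t3"))
  cfg2 <- filter_config(1, 0.5, TRUE, seed = 100)
  c_ <- apply_locus_filters(gm, pm, cfg2)
  # a different seed is allowed to choose differently (not asserted), but
  # the choice is always one locus per tag
  expect_equal(ncol(c_$calls), 3)
})

test_that("filter_config validates its invariants", {
  expect_error(filter_config(min_fraction_individuals = 0), "0, 1")
  expect_error(filter_config(min_fraction_individuals = 1.2), "0, 1")
  fx <- make_filter_fixture()
  expect_error(apply_locus_filters(fx$gm, fx$pm, filter_config(min_populations = 9)),
               "exceeds")
})
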