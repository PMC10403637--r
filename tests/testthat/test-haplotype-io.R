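test_that("phased VCF is transcribed into the haplotype matrix", {
  path <- withr::local_tempfile(fileext = ".vcf")
  gt <- rbind(c("0|1", "1|1", "0|0"),
              c("0|0", "0|1", "1|0"),
              c("1|1", "0|0", "0|1"),
              c("0|1", "1|0", "0|0"))
  colnames(gt) <- c("A", "B", "C")
  write_toy_vcf(path, "chr1", c(100, 200, 300, 400),
                paste0("rs", 1:4), rep("A", 4), rep("G", 4), gt)
  M <- read_phased_vcf(path)
  expect_identical(dim(M$alleles), c(6L, 4L))
  # subject A: haplotype 1 is column 1 of each GT, haplotype 2 column 2
  expect_identical(M$alleles[1, ], c(0L, 0L, 1L, 0L))
  expect_identical(M$alleles[2, ], c(1L, 0L, 1L, 1L))
  expect_identical(M$alleles[5, ], c(0L, 1L, 0L, 0L))
  expect_identical(M$subject_ids, rep(c("A", "B", "C"), each = 2))
  # region restriction and subject selection
  M2 <- read_phased_vcf(path, region = "chr1:150-350", subjects = c("C", "A"))
  expect_identical(dim(M2$alleles), c(4L, 2L))
  expect_identical(M2$subject_ids[1:2], c("C", "C"))
})

test_that("multiallelic sites are dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  gt <- matrix("0|1", 5, 2, dimnames = list(NULL, c("A", "B")))
  write_toy_vcf(path, "chr1", seq(100, 500, by = 100), paste0("rs", 1:5),
                rep("A", 5), c("G", "G", "G,T", "G", "G"), gt)
  expect_warning(M <- read_phased_vcf(path), "multiallelic")
  expect_identical(ncol(M$alleles), 4L)
  expect_false("rs3" %in% M$snps$id)
})

test_that("missing or unphased genotypes are hard errors naming the site", {
  path <- withr::local_tempfile(fileext = ".vcf")
  gt <- rbind(c("0|1", "1|1"), c("0|0", "./."))
  colnames(gt) <- c("A", "B")
  write_toy_vcf(path, "chr1", c(100, 200), c("rs1", "rs2"),
                c("A", "A"), c("G", "G"), gt)
  expect_error(read_phased_vcf(path), "subject B at chr1:200")
  gt[2, 2] <- "0/1"
  write_toy_vcf(path, "chr1", c(100, 200), c("rs1", "rs2"),
                c("A", "A"), c("G", "G"), gt)
  expect_error(read_phased_vcf(path), "unphased")
})

test_that("region strings accept thousands separators and closed bounds", {
  r <- parse_region("chr11:69,419,318-69,616,860")
  expect_identical(r$chrom, "chr11")
  expect_identical(r$start, 69419318)
  expect_identical(r$end, 69616860)
  expect_error(parse_region("chr1:200-100"), "exceeds")
  expect_error(parse_region("chr1"), "malformed")
})

test_that("symmetric reduction trims ends alternately, leftmost first", {
  M <- toy_matrix(random_binary_matrix(4, 62))
  expect_identical(reduce_region_symmetric(toy_matrix(
    random_binary_matrix(4, 57)), 60)$snps$pos, toy_snps(57)$pos)
  r60 <- reduce_region_symmetric(M, 60)
  expect_identical(r60$snps$pos, 100 * (2:61))   # one from each end
  M61 <- toy_matrix(random_binary_matrix(4, 61))
  r <- reduce_region_symmetric(M61, 60)
  expect_identical(r$snps$pos, 100 * (2:61))     # leftmost only
  # idempotent at the target size; order preserved
  expect_identical(reduce_region_symmetric(r60, 60), r60)
  expect_true(all(diff(r60$snps$pos) > 0))
})

test_that("unique haplotypes tally multiplicities over all rows", {
  M <- toy_matrix(rbind(c(0, 1, 0, 1), c(0, 1, 0, 1),
                        c(0, 1, 1, 1), c(0, 1, 0, 1)))
  u <- unique_haplotypes(M)
  expect_identical(u$haplotype, c("0101", "0111"))
  expect_identical(u$count, c(3L, 1L))
  expect_identical(sum(u$count), nrow(M$alleles))
  # all rows identical -> single entry with multiplicity 2n
  M2 <- toy_matrix(matrix(1L, 6, 3))
  expect_identical(unique_haplotypes(M2)$count, 6L)
  # all distinct -> one entry each
  M3 <- toy_matrix(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  expect_identical(unique_haplotypes(M3)$count, rep(1L, 4))
})

test_that("the TSV dialect round-trips a matrix bit-exactly", {
  set.seed(5)
  M <- toy_matrix(random_binary_matrix(8, 7))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_tsv(M, path)
  M2 <- read_haplotype_tsv(path)
  expect_identical(M2$alleles, M$alleles)
  expect_identical(M2$subject_ids, M$subject_ids)
  expect_equal(M2$snps, M$snps)
})

test_that("phased VCF writer round-trips through the reader", {
  set.seed(6)
  cfg <- simulation_config(n_subjects = 5, m_snps = 6, seed = 2,
                           n_covariates = 0L)
  M <- simulate_haplotypes(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_phased_vcf(M, path)
  M2 <- read_phased_vcf(path)
  expect_identical(M2$alleles, M$alleles)
  expect_identical(M2$subject_ids, M$subject_ids)
})

test_that("subject tables validate structure and read from TSV", {
  s <- toy_subjects(c(TRUE, FALSE), n_cov = 2)
  expect_identical(covariate_columns(s), c("cov1", "cov2"))
  expect_error(subject_table(c("a", "a"), c(TRUE, FALSE), c(50, 60)),
               "duplicate")
  expect_error(subject_table("a", TRUE, -1), "positive")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype_tsv(s, path)
  s2 <- read_phenotype_tsv(path)
  expect_identical(s2$case_status, s$case_status)
  expect_equal(s2$cov1, s$cov1)
})
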