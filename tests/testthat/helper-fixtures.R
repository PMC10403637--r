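# shared fixture builders: everything is generated in code at test time

toy_matrix <- function(rows, subject_ids = NULL) {
  rows <- as.matrix(rows)
  n <- nrow(rows)
  stopifnot(n %% 2 == 0)
  if (is.null(subject_ids)) {
    subject_ids <- rep(sprintf("S%02d", seq_len(n / 2)), each = 2)
  }
  haplotype_matrix(rows, subject_ids, toy_snps(ncol(rows)))
}

toy_snps <- function(m) {
  data.frame(chrom = "chr1", pos = 100 * seq_len(m),
             id = paste0("rs", seq_len(m)), ref = "A", alt = "G",
             genotyped = TRUE, stringsAsFactors = FALSE)
}

toy_subjects <- function(case_status, age = NULL, n_cov = 0) {
  n <- length(case_status)
  if (is.null(age)) age <- ifelse(case_status, 55, 65)
  subject_table(sprintf("S%02d", seq_len(n)), case_status, age,
                if (n_cov) matrix(stats::rnorm(n * n_cov), n, n_cov))
}

# minimal phased VCF writer for fixture construction
write_toy_vcf <- function(path, chrom, pos, id, ref, alt, gt) {
  # gt: variants x samples character matrix like "0|1"
  samples <- colnames(gt)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (v in seq_along(pos)) {
    lines <- c(lines, paste(c(chrom, pos[v], id[v], ref[v], alt[v], ".",
                              "PASS", ".", "GT", gt[v, ]), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

random_binary_matrix <- function(n, m, p = 0.5) {
  matrix(stats::rbinom(n * m, 1L, p), n, m)
}
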