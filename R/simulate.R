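#' Simulation configuration
#'
#' Describes a phased case-control cohort to generate: a founder-mosaic
#' background with decaying pairwise LD, embedded (possibly noncontiguous)
#' risk haplotypes painted on randomly chosen chromosomes, and a phenotype
#' model -- logistic with a baseline prevalence (case-control designs) or an
#' age-at-onset model with a baseline hazard and censoring-age distribution
#' (cohort designs).
#'
#' @param n_subjects Number of subjects (twice as many chromosomes).
#' @param m_snps Number of biallelic SNPs.
#' @param allele_freq_range Range the founder alternate-allele frequencies
#'   are drawn from.
#' @param ld_decay Per-step probability of keeping the current founder while
#'   walking along the chromosome; 0 gives independent SNPs, values near 1
#'   give long shared segments and strong adjacent-SNP LD.
#' @param n_founders Size of the founder haplotype pool.
#' @param embedded List of embedded risk haplotypes, each a list with
#'   `pattern` (a [hap_pattern()]), `frequency` (target carrier-chromosome
#'   frequency), `effect` (odds/hazard ratio per copy) and optionally
#'   `ibd` (default `FALSE`): when `TRUE` the carriers are identical by
#'   descent -- they all copy one ancestral background chromosome carrying
#'   the pattern, the way a recent rare haplotype is shared in real
#'   cohorts; when `FALSE` the pattern is painted over each carrier's own
#'   background, giving diverse carriers as for an old common haplotype.
#' @param outcome List: either `list(model = "logistic", prevalence = p)` or
#'   `list(model = "onset", baseline_hazard = h, censor_mean = 65,
#'   censor_sd = 8)`.
#' @param n_covariates Number of standard-normal covariates (no effect on
#'   outcome unless `covariate_effect` is nonzero).
#' @param covariate_effect Common log-scale effect of each covariate.
#' @param seed Mandatory integer seed.
#' @export
simulation_config <- function(n_subjects, m_snps,
                              allele_freq_range = c(0.1, 0.9),
                              ld_decay = 0.9, n_founders = 12L,
                              embedded = list(),
                              outcome = list(model = "logistic",
                                             prevalence = 0.5),
                              n_covariates = 10L, covariate_effect = 0,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_subjects >= 1, m_snps >= 1, ld_decay >= 0, ld_decay <= 1)
  for (e in embedded) {
    stopifnot(inherits(e$pattern, "hap_pattern"),
              e$frequency > 0, e$frequency < 1, e$effect > 0)
    if (length(e$pattern$snp) && max(e$pattern$snp) >= m_snps) {
      stop("embedded pattern touches SNP index beyond m_snps")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 m_snps = as.integer(m_snps),
                 allele_freq_range = allele_freq_range,
                 ld_decay = ld_decay, n_founders = as.integer(n_founders),
                 embedded = embedded, outcome = outcome,
                 n_covariates = as.integer(n_covariates),
                 covariate_effect = covariate_effect,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate phased chromosomes
#'
#' Each chromosome is a first-order mosaic of a small founder-haplotype
#' pool: it copies its current founder's allele and switches founders with
#' probability `1 - ld_decay` at each step, producing pairwise LD that
#' decays with distance plus the haplotype-sharing (subset/superset)
#' structure a pattern miner must disentangle.  Embedded patterns are then
#' painted onto chromosomes drawn independently at the target frequency, so
#' their SNPs interleave with non-pattern columns.  Chromosomes are
#' independent across (and within) subjects.
#'
#' @param config A [simulation_config()].
#' @return A [haplotype_matrix()] with synthetic SNP metadata (positions
#'   1000, 2000, ...; ids `snp1..snpm`).
#' @export
simulate_haplotypes <- function(config) {
  set.seed(config$seed)
  n2 <- 2L * config$n_subjects
  m <- config$m_snps
  K <- config$n_founders
  freqs <- stats::runif(m, config$allele_freq_range[1],
                        config$allele_freq_range[2])
  founders <- matrix(stats::rbinom(K * m, 1L, rep(freqs, each = K)), K, m)
  f <- matrix(0L, n2, m)
  f[, 1] <- sample.int(K, n2, replace = TRUE)
  if (m > 1) {
    for (k in 2:m) {
      switch_ <- stats::runif(n2) > config$ld_decay
      f[, k] <- ifelse(switch_, sample.int(K, n2, replace = TRUE), f[, k - 1])
    }
  }
  X <- matrix(0L, n2, m)
  for (k in seq_len(m)) X[, k] <- founders[f[, k], k]
  for (e in config$embedded) {
    carrier <- stats::runif(n2) < e$frequency
    if (!any(carrier)) next
    if (isTRUE(e$ibd)) {
      # identical-by-descent carriers: one ancestral chromosome, shared
      ancestral <- X[sample(which(!carrier), 1L), ]
      ancestral[e$pattern$snp + 1L] <- e$pattern$allele
      X[carrier, ] <- matrix(ancestral, sum(carrier), m, byrow = TRUE)
    } else {
      X[carrier, e$pattern$snp + 1L] <-
        matrix(e$pattern$allele, sum(carrier), length(e$pattern$snp),
               byrow = TRUE)
    }
  }
  subj <- sprintf("S%05d", seq_len(config$n_subjects))
  haplotype_matrix(
    X, rep(subj, each = 2),
    data.frame(chrom = "chrS", pos = 1000 * seq_len(m),
               id = paste0("snp", seq_len(m)), ref = "A", alt = "G",
               genotyped = TRUE, stringsAsFactors = FALSE))
}

#' Simulate phenotypes for a simulated cohort
#'
#' Computes each subject's copy number of every embedded pattern and draws
#' case status (and ages) under the configured outcome model with additive
#' per-copy log effects, mirroring the dosage models used in the analysis.
#'
#' @param matrix A [haplotype_matrix()] from [simulate_haplotypes()].
#' @param config The same [simulation_config()].
#' @return A [subject_table()].
#' @export
simulate_phenotypes <- function(matrix, config) {
  set.seed(config$seed + 1L)
  subj <- unique(matrix$subject_ids)
  n <- length(subj)
  copies <- vapply(config$embedded, function(e) {
    carr <- pattern_carriers(e$pattern, matrix)
    as.integer(tapply(carr, matrix$subject_ids, sum)[subj])
  }, integer(n))
  if (!length(config$embedded)) copies <- matrix(0L, n, 0)
  covs <- matrix(stats::rnorm(n * config$n_covariates), n,
                 config$n_covariates)
  loges <- vapply(config$embedded, function(e) log(e$effect), numeric(1))
  score <- as.numeric(copies %*% loges) +
    config$covariate_effect * rowSums(covs)
  out <- config$outcome
  if (identical(out$model, "logistic")) {
    eta <- stats::qlogis(out$prevalence) + score
    case <- stats::runif(n) < stats::plogis(eta)
    age <- ifelse(case,
                  stats::rnorm(n, 56.2, 8.6),
                  stats::rnorm(n, 65.0, 7.9))
  } else if (identical(out$model, "onset")) {
    lambda <- out$baseline_hazard * exp(score)
    onset <- stats::rexp(n, rate = lambda)
    censor <- stats::rnorm(n, out$censor_mean %||% 65, out$censor_sd %||% 8)
    case <- onset < censor
    age <- ifelse(case, onset, censor)
  } else {
    stop("unknown outcome model: ", out$model)
  }
  subject_table(subj, case, pmax(age, 1),
                if (config$n_covariates) covs else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full cohort
#'
#' @param config A [simulation_config()].
#' @return List with `matrix`, `subjects` and the `config`.
#' @export
simulate_cohort <- function(config) {
  matrix <- simulate_haplotypes(config)
  list(matrix = matrix, subjects = simulate_phenotypes(matrix, config),
       config = config)
}

#' Write a haplotype matrix as a phased VCF
#'
#' Minimal VCFv4.2 with phased GT fields, consumable by
#' [read_phased_vcf()].
#'
#' @param matrix A [haplotype_matrix()].
#' @param path Output path.
#' @export
write_phased_vcf <- function(matrix, path) {
  subj <- unique(matrix$subject_ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", subj), collapse = "\t")), con)
  s <- matrix$snps
  r1 <- seq(1, nrow(matrix$alleles), by = 2)
  gt <- matrix(paste(t(matrix$alleles[r1, , drop = FALSE]),
                     t(matrix$alleles[r1 + 1, , drop = FALSE]), sep = "|"),
               nrow = ncol(matrix$alleles))
  lines <- paste(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Write a phenotype TSV
#'
#' @param subjects A [subject_table()].
#' @param path Output path.
#' @export
write_phenotype_tsv <- function(subjects, path) {
  df <- as.data.frame(subjects)
  df$case_status <- as.integer(df$case_status)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
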