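test_that("simulation is reproducible and validates its configuration", {
  cfg <- simulation_config(n_subjects = 50, m_snps = 10, seed = 7)
  expect_identical(simulate_haplotypes(cfg)$alleles,
                   simulate_haplotypes(cfg)$alleles)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$subjects, co2$subjects)
  expect_error(simulation_config(n_subjects = 10, m_snps = 5), "seed")
  expect_error(simulation_config(
    n_subjects = 10, m_snps = 5, seed = 1,
    embedded = list(list(pattern = hap_pattern(7, 1), frequency = 0.1,
                         effect = 2))), "beyond m_snps")
})

test_that("ld_decay = 0 gives independent adjacent SNPs", {
  cfg <- simulation_config(n_subjects = 3000, m_snps = 10, ld_decay = 0,
                           n_founders = 40L, seed = 17)
  M <- simulate_haplotypes(cfg)
  r2 <- vapply(1:9, function(k) {
    suppressWarnings(stats::cor(M$alleles[, k], M$alleles[, k + 1])^2)
  }, numeric(1))
  expect_lt(max(r2, na.rm = TRUE), 0.01)
})

test_that("high ld_decay produces substantial adjacent-SNP correlation", {
  cfg <- simulation_config(n_subjects = 3000, m_snps = 10, ld_decay = 0.98,
                           seed = 19)
  M <- simulate_haplotypes(cfg)
  r2 <- vapply(1:9, function(k) {
    stats::cor(M$alleles[, k], M$alleles[, k + 1])^2
  }, numeric(1))
  # founder-pool LD scales like 1/n_founders (12 here); well above the
  # independence limit checked above
  expect_gt(mean(r2), 0.05)
})

test_that("embedded pattern frequency lands in its binomial interval", {
  # a long pattern, so background rows match only with negligible chance
  p <- hap_pattern(0:15, rep(c(1L, 0L), 8))
  cfg <- simulation_config(
    n_subjects = 10000, m_snps = 16, ld_decay = 0.5,
    embedded = list(list(pattern = p, frequency = 50 / 10000, effect = 1)),
    seed = 23)
  M <- simulate_haplotypes(cfg)
  carriers <- sum(pattern_carriers(p, M))
  ci <- stats::qbinom(c(0.005, 0.995), 20000, 50 / 10000)
  # painted carriers plus background-matching rows can only add a few
  expect_gte(carriers, ci[1])
  expect_lte(carriers, ci[2] + 10)
})

test_that("null phenotypes are independent of embedded copies", {
  p <- hap_pattern(c(1, 5), c(1, 1))
  rejections <- vapply(1:30, function(i) {
    cfg <- simulation_config(
      n_subjects = 400, m_snps = 8,
      embedded = list(list(pattern = p, frequency = 0.3, effect = 1)),
      outcome = list(model = "logistic", prevalence = 0.4),
      n_covariates = 0L, seed = 3000 + i)
    co <- simulate_cohort(cfg)
    cp <- pattern_support(p, co$matrix, co$subjects)$copies
    suppressWarnings(stats::chisq.test(table(cp > 0,
                                       co$subjects$case_status))$p.value) < 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.1)
})

test_that("onset model produces cases younger than censored controls", {
  cfg <- simulation_config(
    n_subjects = 2000, m_snps = 6,
    outcome = list(model = "onset", baseline_hazard = 0.006,
                   censor_mean = 65, censor_sd = 8),
    n_covariates = 0L, seed = 29)
  co <- simulate_cohort(cfg)
  s <- co$subjects
  expect_gt(sum(s$case_status), 100)
  expect_lt(mean(s$age[s$case_status]), mean(s$age[!s$case_status]))
  expect_true(all(s$age > 0))
})

test_that("allele-frequency spectrum respects the configured range", {
  cfg <- simulation_config(n_subjects = 4000, m_snps = 20,
                           allele_freq_range = c(0.3, 0.7),
                           n_founders = 30L, ld_decay = 0.5, seed = 31)
  M <- simulate_haplotypes(cfg)
  freq <- colMeans(M$alleles)
  # founder sampling widens the range a little; bulk must sit inside
  expect_gt(mean(freq > 0.15 & freq < 0.85), 0.9)
})
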