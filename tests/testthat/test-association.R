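test_that("two-sided exact test matches published summary tables", {
  # published counts with consistent denominators reproduce the printed
  # p-values at their displayed precision
  expect_equal(signif(fisher_exact(count_table2x2(26, 18022, 116, 344046)), 2),
               8.9e-9)
  expect_equal(signif(fisher_exact(count_table2x2(59, 18022, 371, 344046)), 2),
               2.9e-12)
  expect_equal(fisher_exact(count_table2x2(1, 10, 1, 10)), 1.0)
})

test_that("exact test agrees with stats::fisher.test across random tables", {
  set.seed(7)
  for (i in 1:200) {
    n1 <- sample(2:60, 1)
    n0 <- sample(2:60, 1)
    a <- sample(0:n1, 1)
    b <- sample(0:n0, 1)
    if ((a + b) %in% c(0, n1 + n0)) next
    ours <- fisher_p_vec(a, n1, b, n0)
    ref <- stats::fisher.test(matrix(c(a, n1 - a, b, n0 - b), 2,
                                     byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("exact test agrees with direct hypergeometric summation", {
  # independent oracle: enumerate the support and apply the
  # point-probability rule directly
  direct <- function(a, n1, b, n0) {
    K <- a + b
    k <- max(0, K - n0):min(K, n1)
    pk <- exp(lchoose(n1, k) + lchoose(n0, K - k) - lchoose(n1 + n0, K))
    sum(pk[pk <= pk[k == a] * (1 + 1e-7)])
  }
  set.seed(13)
  for (i in 1:100) {
    n1 <- sample(1:40, 1); n0 <- sample(1:40, 1)
    a <- sample(0:n1, 1); b <- sample(0:n0, 1)
    if ((a + b) %in% c(0, n1 + n0)) next
    expect_equal(fisher_p_vec(a, n1, b, n0), direct(a, n1, b, n0),
                 tolerance = 1e-10)
  }
})

test_that("exact test is invariant to swapping rows with columns", {
  set.seed(17)
  for (i in 1:50) {
    x <- sample(1:30, 4, replace = TRUE)
    p1 <- fisher_p_vec(x[1], x[1] + x[2], x[3], x[3] + x[4])
    p2 <- fisher_p_vec(x[1], x[1] + x[3], x[2], x[2] + x[4])
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("degenerate margins give p = 1 with a warning", {
  expect_warning(p <- fisher_exact(count_table2x2(0, 10, 0, 12)),
                 "degenerate")
  expect_identical(p, 1)
})

test_that("per-10,000 frequencies reproduce the published displays", {
  tab <- published_haplotype_counts()
  ok <- !tab$flagged
  case_disp <- mapply(function(c, t, d) display_per_10k(per_10k(c, t), d),
                      tab$case_carrier[ok], tab$case_total[ok],
                      tab$display_digits[ok])
  expect_equal(case_disp, tab$printed_case_per10k[ok])
  okc <- ok & !tab$control_freq_inconsistent
  ctrl_disp <- mapply(function(c, t, d) display_per_10k(per_10k(c, t), d),
                      tab$control_carrier[okc], tab$control_total[okc],
                      tab$display_digits[okc])
  expect_equal(ctrl_disp, tab$printed_control_per10k[okc])
  expect_identical(per_10k(0, 100), 0)
})

test_that("conditional exact test equals the hand-built restricted table", {
  M <- toy_matrix(rbind(
    c(1, 1, 0), c(1, 1, 1),   # S01 case, both rows carry h1 = {(0,1)}
    c(1, 0, 0), c(0, 0, 1),   # S02 case
    c(1, 1, 1), c(1, 0, 0),   # S03 control
    c(0, 1, 0), c(1, 0, 1)))  # S04 control
  subj <- toy_subjects(c(TRUE, TRUE, FALSE, FALSE))
  h1 <- hap_pattern(0, 1)
  h <- hap_pattern(c(0, 1), c(1, 1))
  # restricted universe: rows carrying h1 (3 case, 3 control chromosomes)
  p_hand <- fisher_exact(count_table2x2(2, 3, 1, 3))
  expect_equal(conditional_fisher(h, h1, M, subj), p_hand)
  # h == h1: every conditional chromosome is a carrier -> degenerate, p = 1
  expect_warning(expect_identical(conditional_fisher(h1, h1, M, subj), 1))
  expect_error(conditional_fisher(h, hap_pattern(c(0, 1, 2), c(1, 1, 0)),
                                  M, subj), "control chromosomes")
})

test_that("dosage models flag non-informative input", {
  subj <- toy_subjects(rep(c(TRUE, FALSE), 10), n_cov = 1)
  expect_true(cox_lrt(rep(0L, 20), subj)$flagged)
  expect_true(logistic_lrt(rep(0L, 20), subj)$flagged)
})

test_that("crude logistic odds ratio equals the table cross-product ratio", {
  # closed-form check: no covariates, binary dose
  counts <- c(a = 18, b = 22, c = 7, d = 33)  # case/ctrl x carrier/non
  dose <- c(rep(1, counts["a"]), rep(0, counts["b"]),
            rep(1, counts["c"]), rep(0, counts["d"]))
  case <- c(rep(TRUE, counts["a"] + counts["b"]),
            rep(FALSE, counts["c"] + counts["d"]))
  fit <- stats::glm(case ~ dose, family = stats::binomial())
  expect_equal(unname(exp(stats::coef(fit)["dose"])),
               (18 * 33) / (22 * 7), tolerance = 1e-8)
})

test_that("cox and logistic dosage models recover simulated effects", {
  p <- hap_pattern(c(1, 4), c(1, 0))
  cfg <- simulation_config(
    n_subjects = 3000, m_snps = 8, ld_decay = 0.5,
    embedded = list(list(pattern = p, frequency = 0.2, effect = 2.0)),
    outcome = list(model = "onset", baseline_hazard = 0.006,
                   censor_mean = 65, censor_sd = 8),
    n_covariates = 2, seed = 91)
  co <- simulate_cohort(cfg)
  cp <- pattern_support(p, co$matrix, co$subjects)$copies
  fit <- cox_lrt(cp, co$subjects)
  expect_false(fit$flagged)
  expect_lt(abs(log(fit$effect) - log(2)), 1.96 * fit$se_log_effect + 0.2)
  expect_lt(fit$lrt_p, 1e-6)
  cfg2 <- simulation_config(
    n_subjects = 3000, m_snps = 8, ld_decay = 0.5,
    embedded = list(list(pattern = p, frequency = 0.2, effect = 2.0)),
    outcome = list(model = "logistic", prevalence = 0.3),
    n_covariates = 2, seed = 92)
  co2 <- simulate_cohort(cfg2)
  cp2 <- pattern_support(p, co2$matrix, co2$subjects)$copies
  fit2 <- logistic_lrt(cp2, co2$subjects)
  expect_false(fit2$flagged)
  expect_lt(abs(log(fit2$effect) - log(2)), 3 * fit2$se_log_effect)
})

test_that("permuting onset ages under the null keeps the LRT p uniform-ish", {
  set.seed(101)
  subj <- toy_subjects(rep(c(TRUE, FALSE), 150),
                       age = c(stats::runif(300, 40, 75)))
  ps <- replicate(40, {
    dose <- stats::rbinom(300, 2, 0.2)
    cox_lrt(dose, subj)$lrt_p
  })
  # under the null, small p-values are not enriched
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(min(ps), 1e-4)
})

test_that("stepwise forward selection is greedy with an entry gate", {
  set.seed(61)
  n <- 800
  subj <- toy_subjects(rep(c(TRUE, FALSE), n / 2),
                       age = stats::runif(n, 40, 75))
  causal <- stats::rbinom(n, 1, 0.3)
  # outcome driven by `causal` only; `shadow` is a noisy copy
  case <- stats::rbinom(n, 1, stats::plogis(-1 + 1.5 * causal)) == 1
  subj$case_status <- case
  shadow <- ifelse(stats::runif(n) < 0.8, causal, stats::rbinom(n, 1, 0.3))
  noise <- stats::rbinom(n, 1, 0.3)
  sel <- stepwise_forward(list(causal = causal, shadow = shadow,
                               noise = noise),
                          subjects = subj, entry_p = 1e-4,
                          model = "logistic")
  expect_identical(sel[1], "causal")
  expect_false("noise" %in% sel)
  # nothing qualifies under an impossible gate
  expect_identical(stepwise_forward(list(noise = noise), subjects = subj,
                                    entry_p = 1e-30, model = "logistic"),
                   character(0))
})

test_that("LD metrics match their algebraic forms", {
  a <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  r <- ld_metrics(a, a)
  expect_equal(r$r2, 1)
  expect_equal(r$d_prime, 1)
  # nested carriers: D' = 1 and r2 = pa(1-pb) / (pb(1-pa))
  set.seed(71)
  b <- stats::rbinom(4000, 1, 0.4) == 1
  a2 <- b & stats::rbinom(4000, 1, 0.5) == 1
  r2 <- ld_metrics(a2, b)
  pa <- mean(a2); pb <- mean(b)
  expect_equal(r2$d_prime, 1, tolerance = 1e-9)
  expect_equal(r2$r2, pa * (1 - pb) / (pb * (1 - pa)), tolerance = 1e-9)
  # independent vectors: r2 near zero for large n
  ind <- stats::rbinom(4000, 1, 0.5) == 1
  expect_lt(ld_metrics(ind, b)$r2, 0.01)
  expect_error(ld_metrics(rep(TRUE, 5), c(TRUE, rep(FALSE, 4))),
               "monomorphic")
})

test_that("stratified permutations preserve case counts in both strata", {
  carriers <- data.frame(
    subject_id = paste0("S", 1:6),
    case_status = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
    copies = c(1L, 1L, 1L, 1L, 2L, 2L))
  perms <- permutation_null(carriers, 50, seed = 5)
  for (j in 1:50) {
    expect_identical(sum(perms[carriers$copies == 1, j]), 2L)
    expect_identical(sum(perms[carriers$copies == 2, j]), 1L)
  }
  # exhaustive support: all C(4,2) x C(2,1) = 12 assignments appear
  big <- permutation_null(carriers, 400, seed = 6)
  expect_identical(nrow(unique(t(big))), 12L)
  # identity when every carrier is a case; reproducible under the seed
  all_case <- carriers; all_case$case_status <- TRUE
  expect_true(all(permutation_null(all_case, 3, seed = 1)))
  expect_identical(permutation_null(carriers, 10, seed = 9),
                   permutation_null(carriers, 10, seed = 9))
})
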