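#' Simulation-study checks of the mining engine and pipeline
#'
#' These routines run the package end to end under controlled synthetic
#' conditions and summarize the outcome as a single rate, so that the same
#' computation backs both the test suite and the reproducibility script.
#' Problem sizes are chosen to make each check decisive yet quick on one
#' CPU; the methods vignette discusses the choices.
#'
#' @name validation
NULL

#' Agreement of the iterative miner with the brute-force oracle
#'
#' Draws random haplotype instances (small enough for exhaustive subset
#' enumeration), runs the iterated pairwise overlap with no filtering, and
#' compares the discovered closed-pattern set (patterns shared by at least
#' two seeds) with the brute-force all-subset intersections.
#'
#' @param n_instances Number of random instances.
#' @param seed Integer seed.
#' @param max_rows,max_snps Upper bounds for the random instance sizes.
#' @return Fraction of instances with exact set agreement.
#' @export
oracle_agreement <- function(n_instances = 200L, seed = 1L,
                             max_rows = 12L, max_snps = 16L) {
  set.seed(seed)
  ok <- logical(n_instances)
  for (i in seq_len(n_instances)) {
    n <- sample(2:max_rows, 1)
    m <- sample(3:max_snps, 1)
    X <- matrix(stats::rbinom(n * m, 1L, stats::runif(1, 0.2, 0.8)), n, m)
    X <- unique(X)
    seeds <- lapply(seq_len(nrow(X)), function(r) {
      meta_chromosome(dense_to_pattern(X[r, ]), comprised = r)
    })
    mined <- mine_closed_patterns(seeds, sigma = 2L, m = m)
    ok[i] <- identical(sort(mined_closed_set(mined)),
                       brute_force_closed_patterns(X, min_support = 2L))
  }
  mean(ok)
}

#' Index/combination bijection check
#'
#' For every `N` and `sigma` in range, decodes the full flat-index range and
#' compares the tuple list with the lexicographic enumeration
#' (`utils::combn`), and round-trips each tuple through
#' [combination_to_index()].
#'
#' @param max_N,max_sigma Ranges to check.
#' @return Fraction of (N, sigma) cells that pass (1 when the bijection is
#'   exact everywhere).
#' @export
bijection_agreement <- function(max_N = 12L, max_sigma = 5L) {
  cells <- 0L
  pass <- 0L
  for (N in 1:max_N) for (sg in 1:min(max_sigma, N)) {
    cells <- cells + 1L
    ref <- t(utils::combn(N, sg))
    dec <- matrix(vapply(seq_len(nrow(ref)) - 1L,
                         function(I) index_to_combination(I, N, sg),
                         integer(sg)),
                  ncol = sg, byrow = TRUE)
    enc <- vapply(seq_len(nrow(ref)),
                  function(r) combination_to_index(ref[r, ], N), numeric(1))
    if (identical(dec, ref) && identical(enc, as.numeric(0:(nrow(ref) - 1)))) {
      pass <- pass + 1L
    }
  }
  pass / cells
}

#' Telescoping binomial identity check
#'
#' @param max_N Largest `N` checked (all `sigma <= N`).
#' @return Fraction of (N, sigma) pairs where the partial sum equals
#'   `choose(N+1, sigma+1)`.
#' @export
lemma_agreement <- function(max_N = 30L) {
  pairs <- 0L
  pass <- 0L
  for (N in 1:max_N) for (sg in 1:N) {
    pairs <- pairs + 1L
    if (partial_binomial_sum(N, sg) == choose(N + 1, sg + 1)) pass <- pass + 1L
  }
  pass / pairs
}

# study-condition scenario for conditional rare-subtype recovery: an onset
# cohort with a conditioning haplotype (frequency 0.02, OR 1.3) and a rare
# noncontiguous identity-by-descent subtype on ~30 chromosomes, HR 4 per copy
.recovery_config <- function(seed, n_subjects = 20000L) {
  m <- 40L
  set.seed(seed)
  h1_snp <- 20:31
  h1 <- hap_pattern(h1_snp, stats::rbinom(length(h1_snp), 1, 0.5))
  # rare subtypes use most of the region's SNPs; 20 extra alleles also
  # make chance background matches (which would blur the carrier set)
  # vanishingly unlikely
  extra_snp <- sort(sample(c(0:19, 32:39), 20))
  sub <- pattern_union(h1, hap_pattern(extra_snp,
                                       stats::rbinom(20, 1, 0.5)))
  simulation_config(
    n_subjects = n_subjects, m_snps = m, allele_freq_range = c(0.3, 0.7),
    ld_decay = 0.8, n_founders = 16L,
    embedded = list(
      list(pattern = h1, frequency = 0.02, effect = 1.3),
      list(pattern = sub, frequency = 30 / (2 * n_subjects), effect = 4.0,
           ibd = TRUE)),
    # true cohort under the onset model: with ~30 carrier chromosomes at
    # HR 4 the Cox information is ~ the carrier event count, so the
    # study-wide 1e-5 report threshold is within reach
    outcome = list(model = "onset", baseline_hazard = 0.0055,
                   censor_mean = 65, censor_sd = 8),
    n_covariates = 3L, seed = seed)
}

#' Recovery rate of an embedded rare subtype by conditional discovery
#'
#' For each seed, simulates an age-at-onset cohort of `n_subjects` with a
#' conditioning haplotype (frequency 0.02, OR 1.3) and a rare
#' noncontiguous identity-by-descent subtype of it (about 30 carrier
#' chromosomes, hazard ratio 4 per copy), runs [run_phase2()] conditioning
#' on the embedded haplotype, and scores a success when a reported pattern
#' has exactly the subtype's carrier chromosome set.
#'
#' @param n_seeds Number of independent simulated cohorts.
#' @param seed Base seed (cohort i uses `seed * 1000 + i`).
#' @param n_subjects Cohort size.
#' @return List with `rate` and the per-seed logical vector.
#' @export
phase2_recovery <- function(n_seeds = 25L, seed = 1L, n_subjects = 20000L) {
  hit <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- .recovery_config(seed * 1000L + i, n_subjects)
    cohort <- simulate_cohort(cfg)
    h1 <- cfg$embedded[[1]]$pattern
    target <- pattern_carriers(cfg$embedded[[2]]$pattern, cohort$matrix)
    # the iteration-1 cap exists to prevent combinatorial explosion, which
    # this problem size never approaches; the same-frequency family rule
    # is off because it exists to damp growth that primary filtering
    # cannot contain (and can discard a rare family's own members)
    ph2 <- tryCatch(
      run_phase2(cohort$matrix, cohort$subjects, h1,
                 phase_config(max_snps = 200L, p_threshold = 0.05,
                              max_keep = 25L, family_rule = FALSE,
                              candidate_p = 0.01, entry_p = 1e-5,
                              max_candidates = 600L, stepwise_max = 15L)),
      error = function(e) NULL)
    if (!is.null(ph2) && nrow(ph2$reported)) {
      hit[i] <- any(vapply(names(ph2$patterns), function(k) {
        identical(pattern_carriers(ph2$patterns[[k]], cohort$matrix), target)
      }, logical(1)))
    }
  }
  list(rate = mean(hit), hits = hit)
}

#' Confidence-interval coverage of the logistic dosage model
#'
#' Simulates case-control cohorts with one embedded common haplotype of
#' known odds ratio and checks how often the Wald 95% interval for the
#' per-copy log odds ratio covers the truth.
#'
#' @param n_reps Number of replicates.
#' @param seed Base seed.
#' @param n_subjects Subjects per replicate.
#' @param odds_ratio True per-copy odds ratio.
#' @return List with `coverage` and the per-replicate logical vector.
#' @export
logistic_coverage <- function(n_reps = 200L, seed = 1L, n_subjects = 2000L,
                              odds_ratio = 2.0) {
  p <- hap_pattern(c(2, 5, 9), c(1, 0, 1))
  covered <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- simulation_config(
      n_subjects = n_subjects, m_snps = 12L, ld_decay = 0.9,
      embedded = list(list(pattern = p, frequency = 0.15,
                           effect = odds_ratio)),
      outcome = list(model = "logistic", prevalence = 0.3),
      n_covariates = 2L, seed = seed * 1000L + i)
    cohort <- simulate_cohort(cfg)
    cp <- pattern_support(p, cohort$matrix, cohort$subjects)$copies
    fit <- logistic_lrt(cp, cohort$subjects)
    if (!isTRUE(fit$flagged) && is.finite(fit$se_log_effect)) {
      lo <- log(fit$effect) - 1.96 * fit$se_log_effect
      hi <- log(fit$effect) + 1.96 * fit$se_log_effect
      covered[i] <- lo <= log(odds_ratio) && log(odds_ratio) <= hi
    }
  }
  list(coverage = mean(covered), covered = covered)
}

# fully null cohort (an effect-free common haplotype is still embedded so
# that conditional analyses have a conditioning pattern)
.null_config <- function(seed, n_subjects = 1500L, m = 24L) {
  set.seed(seed)
  h1_snp <- 14:21
  h1 <- hap_pattern(h1_snp, stats::rbinom(length(h1_snp), 1, 0.5))
  simulation_config(
    n_subjects = n_subjects, m_snps = m, ld_decay = 0.95, n_founders = 10L,
    embedded = list(list(pattern = h1, frequency = 0.15, effect = 1.0)),
    outcome = list(model = "onset", baseline_hazard = 0.0055,
                   censor_mean = 65, censor_sd = 8),
    n_covariates = 2L, seed = seed)
}

#' Null calibration of the two-phase pipeline
#'
#' On cohorts with no genotype-phenotype association: (1) marginal
#' discovery should halt with no candidate passing the admission threshold;
#' (2) the permutation-based false-positive replication estimate should be
#' small (or undefined for lack of permuted discoveries), mirroring the
#' single-digit-percent chance-replication rates such permutation analyses
#' produce.
#'
#' @param n_seeds Cohorts for the halt check.
#' @param seed Base seed.
#' @param n_permutations Permutations for the false-positive estimate.
#' @return List with `halt_rate`, `fpr` (fraction or `NA`), `n_discovered`.
#' @export
null_calibration <- function(n_seeds = 5L, seed = 1L, n_permutations = 8L) {
  halted <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    cohort <- simulate_cohort(.null_config(seed * 1000L + i))
    ph1 <- run_phase1(cohort$matrix, cohort$subjects,
                      phase_config(max_snps = 60L, p_threshold = 1e-4,
                                   max_keep = 100L, candidate_p = 1e-8))
    halted[i] <- ph1$halted
  }
  cfg <- .null_config(seed * 1000L + n_seeds + 1L)
  cohort <- simulate_cohort(cfg)
  repl <- simulate_cohort(.null_config(seed * 1000L + n_seeds + 2L))
  fpr <- estimate_false_positive_rate(
    cohort$matrix, cohort$subjects, cfg$embedded[[1]]$pattern,
    phase_config(max_snps = 200L, p_threshold = 1e-4, max_keep = 30L,
                 family_rule = TRUE, candidate_p = 1e-4, entry_p = 1e-5,
                 max_candidates = 100L),
    repl$matrix, repl$subjects, n_permutations = n_permutations,
    seed = seed)
  list(halt_rate = mean(halted), fpr = fpr$fraction,
       n_discovered = fpr$n_discovered)
}
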