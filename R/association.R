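#' 2x2 chromosome count tables
#'
#' Carrier versus non-carrier chromosome counts split by case status.
#' Chromosomes (two per subject) are the units of the exact tests; the
#' regression models use per-subject copy numbers instead.
#'
#' @param case_carrier,control_carrier Carrier chromosome counts.
#' @param case_total,control_total Total chromosome counts per arm.
#' @export
count_table2x2 <- function(case_carrier, case_total,
                           control_carrier, control_total) {
  if (case_carrier > case_total || control_carrier > control_total ||
      min(case_carrier, control_carrier, case_total, control_total) < 0) {
    stop("invalid 2x2 chromosome counts")
  }
  structure(list(case_carrier = case_carrier,
                 case_noncarrier = case_total - case_carrier,
                 control_carrier = control_carrier,
                 control_noncarrier = control_total - control_carrier),
            class = "count_table2x2")
}

#' Two-sided Fisher's exact test on chromosome counts
#'
#' Exact hypergeometric test with two-sidedness by the point-probability
#' rule: the p-value sums the probabilities of all tables (at the observed
#' margins) whose point probability does not exceed the observed one (up to
#' the customary 1e-7 relative tolerance).  This is the convention of
#' standard exact-test implementations and is cross-checked against
#' `stats::fisher.test` in the package tests.  A degenerate margin gives
#' p = 1 with a warning.
#'
#' @param table A [count_table2x2()].
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(count_table2x2(26, 18022, 116, 344046))
#' @export
fisher_exact <- function(table) {
  stopifnot(inherits(table, "count_table2x2"))
  fisher_p_vec(table$case_carrier,
               table$case_carrier + table$case_noncarrier,
               table$control_carrier,
               table$control_carrier + table$control_noncarrier)
}

#' @rdname fisher_exact
#' @param case_carrier,control_carrier Vectors of carrier chromosome counts.
#' @param case_total,control_total Chromosome totals (recycled).
#' @export
fisher_p_vec <- function(case_carrier, case_total,
                         control_carrier, control_total) {
  n <- max(length(case_carrier), length(control_carrier))
  a <- rep_len(case_carrier, n)
  b <- rep_len(control_carrier, n)
  n1 <- rep_len(case_total, n)
  n0 <- rep_len(control_total, n)
  key <- paste(a, b, n1, n0)
  first <- !duplicated(key)
  p1 <- vapply(which(first), function(i) {
    K <- a[i] + b[i]
    N <- n1[i] + n0[i]
    if (K == 0 || K == N || n1[i] == 0 || n0[i] == 0) {
      warning("degenerate margin in 2x2 table; p = 1")
      return(1)
    }
    lo <- max(0L, K - n0[i])
    hi <- min(K, n1[i])
    pk <- stats::dhyper(lo:hi, n1[i], n0[i], K)
    pobs <- stats::dhyper(a[i], n1[i], n0[i], K)
    min(1, sum(pk[pk <= pobs * (1 + 1e-7)]))
  }, numeric(1))
  p1[match(key, key[first])]
}

#' Haplotype-conditional Fisher's exact test
#'
#' Association of `h` with case status among the chromosomes carrying the
#' conditioning haplotype `h1` only, isolating risk beyond `h1` itself.
#'
#' @param h,h1 Patterns ([hap_pattern()]).
#' @param matrix A [haplotype_matrix()].
#' @param subjects A [subject_table()].
#' @return Two-sided conditional p-value.
#' @export
conditional_fisher <- function(h, h1, matrix, subjects) {
  carr1 <- pattern_carriers(h1, matrix)
  is_case <- subjects$case_status[match(matrix$subject_ids,
                                        subjects$subject_id)]
  if (!any(carr1 & !is_case)) {
    stop("no conditioning-haplotype carriers among control chromosomes")
  }
  carr <- pattern_carriers(h, matrix) & carr1
  fisher_p_vec(sum(carr & is_case), sum(carr1 & is_case),
               sum(carr & !is_case), sum(carr1 & !is_case))
}

#' Carrier frequency per 10,000 chromosomes
#'
#' @param carriers Carrier chromosome count(s).
#' @param total Total chromosome count.
#' @return `carriers / total * 10000`, unrounded; round only for display.
#' @examples
#' per_10k(2100, 18022)  # prints as 1165 at 4 significant digits
#' @export
per_10k <- function(carriers, total) {
  stopifnot(total > 0)
  carriers / total * 1e4
}

#' @rdname per_10k
#' @param x A per-10,000 rate.
#' @param digits Significant digits used for display (the published tables
#'   use 4 for common haplotypes and 3 for rare ones; rates below 1 are
#'   shown to two decimal places).
#' @export
display_per_10k <- function(x, digits = 3) {
  ifelse(x < 1, round(x, 2), signif(x, digits))
}

.subject_model_frame <- function(subjects, copies, baseline_terms) {
  df <- data.frame(case = subjects$case_status, age = subjects$age)
  covs <- covariate_columns(subjects)
  for (cv in covs) df[[cv]] <- subjects[[cv]]
  for (b in seq_along(baseline_terms)) {
    df[[paste0("base", b)]] <- as.numeric(baseline_terms[[b]])
  }
  df$dose <- as.numeric(copies)
  df
}

.assoc_result <- function(effect, lrt_p, model_tag, se = NA_real_,
                          flagged = FALSE, note = NULL) {
  structure(list(effect = effect, se_log_effect = se, lrt_p = lrt_p,
                 model_tag = model_tag, flagged = flagged, note = note),
            class = "assoc_result")
}

# Cox score-test screen: p-values for adding each dosage column to a fixed
# proportional-hazards null model (fitted once), with age as the time axis.
# Breslow-style risk sets are prefix sums over age-sorted subjects, so the
# whole candidate block is screened with a few cumulative-sum passes.  The
# score and likelihood-ratio tests are asymptotically equivalent, so the
# screen orders candidates cheaply before exact LRT evaluation.
.score_screen <- function(D, subjects, baseline_terms = list()) {
  base <- .subject_model_frame(subjects, 0, baseline_terms)
  X0 <- as.matrix(base[, setdiff(names(base), c("case", "age", "dose")),
                       drop = FALSE])
  eta <- if (ncol(X0)) {
    f0 <- .cox_fit(X0, survival::Surv(base$age, base$case))
    if (is.null(f0)) rep(0, nrow(base))
    else as.numeric(X0 %*% f0$coefficients)
  } else rep(0, nrow(base))
  o <- order(base$age, decreasing = TRUE)  # risk sets become prefixes
  w <- exp(eta)[o]
  ev <- which(base$case[o])
  D <- as.matrix(D)[o, , drop = FALSE]
  cumw <- cumsum(w)[ev]
  U <- numeric(ncol(D))
  V <- numeric(ncol(D))
  for (k in seq_len(ncol(D))) {
    d <- D[, k]
    cwd <- cumsum(w * d)[ev]
    cwd2 <- cumsum(w * d * d)[ev]
    dbar <- cwd / cumw
    U[k] <- sum(d[ev] - dbar)
    V[k] <- sum(cwd2 / cumw - dbar^2)
  }
  z2 <- ifelse(V > 1e-12, U^2 / V, 0)
  stats::pchisq(z2, df = 1, lower.tail = FALSE)
}

# direct partial-likelihood fit (skips formula handling and the concordance
# statistic, which dominate coxph() runtime when scoring many candidates)
.cox_fit <- function(X, y) {
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      as.matrix(X), y, strata = NULL, offset = NULL, init = NULL,
      control = survival::coxph.control(), weights = NULL,
      method = "efron", rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients) ||
      any(!is.finite(fit$coefficients))) return(NULL)
  fit
}

# score many dosage vectors against a fixed baseline design with one null
# fit; returns a list of assoc_result
.cox_lrt_batch <- function(copies_list, subjects, baseline_terms = list()) {
  base <- .subject_model_frame(subjects, 0, baseline_terms)
  y <- survival::Surv(base$age, base$case)
  X0 <- as.matrix(base[, setdiff(names(base), c("case", "age", "dose")),
                       drop = FALSE])
  ll0 <- NULL   # with no baseline columns, each fit's own null loglik is used
  if (ncol(X0)) {
    f0 <- .cox_fit(X0, y)
    if (is.null(f0)) return(lapply(copies_list, function(cp) {
      .assoc_result(NA_real_, NA_real_, "cox", flagged = TRUE,
                    note = "baseline non-convergence")
    }))
    ll0 <- f0$loglik[2]
  }
  lapply(copies_list, function(cp) {
    cp <- as.numeric(cp)
    if (!any(base$case) || all(cp == cp[1]) || all(cp[base$case] == 0)) {
      return(.assoc_result(NA_real_, NA_real_, "cox", flagged = TRUE,
                           note = "no informative carriers"))
    }
    f1 <- .cox_fit(cbind(X0, dose = cp), y)
    if (is.null(f1)) {
      return(.assoc_result(NA_real_, NA_real_, "cox", flagged = TRUE,
                           note = "non-convergence"))
    }
    k <- length(f1$coefficients)
    lrt <- 2 * (f1$loglik[2] - if (is.null(ll0)) f1$loglik[1] else ll0)
    .assoc_result(exp(f1$coefficients[k]),
                  stats::pchisq(max(lrt, 0), 1, lower.tail = FALSE),
                  "cox", se = sqrt(f1$var[k, k]))
  })
}

#' Proportional-hazards dosage association with likelihood-ratio test
#'
#' Fits a Cox model with age as the time axis (entry at age 0, event = case
#' at onset age, censoring at end of follow-up for controls), the haplotype
#' copy number (0/1/2) as a continuous additive term, adjusted for the
#' subject covariates and any baseline haplotype terms.  Significance is the
#' one-degree-of-freedom likelihood-ratio test against the same model
#' without the new term.
#'
#' @param copies Per-subject copy numbers (0/1/2), aligned with `subjects`.
#' @param subjects A [subject_table()].
#' @param baseline_terms List of per-subject copy vectors already in the
#'   model (e.g. the phase-1 haplotype during phase 2).
#' @return An association result: `effect` (hazard ratio per copy),
#'   `se_log_effect`, `lrt_p`, `model_tag`, and `flagged` (non-informative
#'   dosage or non-convergence; flagged results are excluded from
#'   selection).
#' @export
cox_lrt <- function(copies, subjects, baseline_terms = list()) {
  .cox_lrt_batch(list(copies), subjects, baseline_terms)[[1]]
}

#' Logistic dosage association with likelihood-ratio test
#'
#' Case-control analogue of [cox_lrt()]: additive copy number in a logistic
#' model with age and the subject covariates (plus any baseline terms) as
#' adjustments; reports the odds ratio per copy and the one-degree-of-freedom
#' LRT p-value against the model without the term.
#'
#' @inheritParams cox_lrt
#' @export
logistic_lrt <- function(copies, subjects, baseline_terms = list()) {
  df <- .subject_model_frame(subjects, copies, baseline_terms)
  if (!any(df$case) || all(df$dose == df$dose[1])) {
    return(.assoc_result(NA_real_, NA_real_, "logistic", flagged = TRUE,
                         note = "no informative carriers"))
  }
  rhs0 <- setdiff(names(df), c("case", "dose"))
  f1 <- stats::reformulate(c(rhs0, "dose"), response = "case")
  f0 <- stats::reformulate(rhs0, response = "case")
  fit1 <- tryCatch(stats::glm(f1, family = stats::binomial(), data = df),
                   error = function(e) NULL)
  if (is.null(fit1) || !is.finite(stats::coef(fit1)["dose"]) ||
      abs(stats::coef(fit1)["dose"]) > 15) {
    return(.assoc_result(NA_real_, NA_real_, "logistic", flagged = TRUE,
                         note = "non-convergence or separation"))
  }
  fit0 <- stats::glm(f0, family = stats::binomial(), data = df)
  lrt <- fit0$deviance - fit1$deviance
  .assoc_result(exp(stats::coef(fit1)["dose"]),
                stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
                "logistic",
                se = sqrt(diag(stats::vcov(fit1))["dose"]))
}

#' Greedy stepwise forward selection of haplotype terms
#'
#' At each round every remaining candidate is tested against the current
#' model; the candidate with the smallest LRT p-value enters if it is below
#' `entry_p`, otherwise selection stops.  An empty selection is valid.
#'
#' @param candidates Named list of per-subject copy vectors.
#' @param base List of copy vectors always in the model (e.g. the common
#'   haplotype).
#' @param subjects A [subject_table()].
#' @param entry_p Entry threshold on the LRT p-value.
#' @param model `"cox"` or `"logistic"`.
#' @return Character vector of selected candidate names, in entry order.
#' @export
stepwise_forward <- function(candidates, base = list(), subjects,
                             entry_p = 1e-5, model = c("cox", "logistic")) {
  model <- match.arg(model)
  fit_fun <- if (model == "cox") cox_lrt else logistic_lrt
  selected <- character(0)
  remaining <- names(candidates)
  if (is.null(remaining) && length(candidates)) {
    remaining <- names(candidates) <- as.character(seq_along(candidates))
  }
  current <- base
  while (length(remaining)) {
    res <- if (model == "cox") {
      .cox_lrt_batch(candidates[remaining], subjects, current)
    } else {
      lapply(remaining, function(nm) {
        fit_fun(candidates[[nm]], subjects, baseline_terms = current)
      })
    }
    p <- vapply(res, function(x) {
      if (isTRUE(x$flagged) || !is.finite(x$lrt_p)) Inf else x$lrt_p
    }, numeric(1))
    best <- which.min(p)
    if (!length(best) || p[best] >= entry_p) break
    selected <- c(selected, remaining[best])
    current <- c(current, candidates[remaining[best]])
    remaining <- remaining[-best]
  }
  selected
}

#' Linkage disequilibrium between two carrier indicators
#'
#' Standard two-locus metrics on binary indicators over the same chromosome
#' universe: `D = p_ab - p_a p_b`, `r^2 = D^2 / (p_a(1-p_a) p_b(1-p_b))`,
#' and `D' = |D| / D_max` with `D_max = min(p_a(1-p_b), p_b(1-p_a))` for
#' positive `D` and `min(p_a p_b, (1-p_a)(1-p_b))` for negative `D`.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return List with `r2` and `d_prime`, both in [0, 1].
#' @export
ld_metrics <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  stopifnot(length(a) == length(b))
  pa <- mean(a)
  pb <- mean(b)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    stop("monomorphic carrier vector; LD undefined")
  }
  D <- mean(a & b) - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  dmax <- if (D >= 0) min(pa * (1 - pb), pb * (1 - pa))
          else min(pa * pb, (1 - pa) * (1 - pb))
  list(r2 = r2, d_prime = if (D == 0) 0 else abs(D) / dmax)
}

#' Stratified permutation null for conditional discovery
#'
#' Reassigns case labels uniformly at random among the carriers of a
#' conditioning haplotype such that the observed numbers of case
#' heterozygotes (1 copy) and case homozygotes (2 copies) are both
#' preserved; non-carriers are untouched.  This keeps the conditioning
#' haplotype's own association intact while destroying any within-carrier
#' structure, giving a null for rare-subtype discovery.
#'
#' @param carriers Data frame with columns `subject_id`, `case_status` and
#'   `copies` (1 or 2) for the carrier subjects.
#' @param n_permutations Number of permutations.
#' @param seed Integer seed; the permutation sequence is reproducible.
#' @return Logical matrix, one row per carrier subject, one column per
#'   permutation, of permuted case labels.
#' @export
permutation_null <- function(carriers, n_permutations, seed) {
  stopifnot(all(carriers$copies %in% c(1L, 2L)))
  set.seed(seed)
  out <- matrix(FALSE, nrow(carriers), n_permutations)
  for (cp in c(1L, 2L)) {
    idx <- which(carriers$copies == cp)
    k <- sum(carriers$case_status[idx])
    if (k > length(idx)) stop("impossible stratum counts")
    for (j in seq_len(n_permutations)) {
      out[idx[sample.int(length(idx), k)], j] <- TRUE
    }
  }
  rownames(out) <- carriers$subject_id
  out
}
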