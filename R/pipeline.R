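#' Filtering policy for iteration-1 meta-chromosomes
#'
#' The initial pairwise overlap is the combinatorial bottleneck of a mining
#' run, so only the patterns most associated with case status are carried
#' into further iterations: a p-value threshold, then a cap on the retained
#' count (deterministic tie-breaking), then optionally a same-frequency
#' family rule that keeps only the fewest-allele member among patterns with
#' identical case/control counts that are not related as subset-superset.
#'
#' @param p_threshold Fisher p cutoff applied at iteration 1.
#' @param max_keep Target retained count (on the order of 100 for marginal
#'   discovery, 30 for conditional discovery).
#' @param family_rule Apply the shortest-member family rule?
#' @export
filter_policy <- function(p_threshold = 1e-4, max_keep = 100L,
                          family_rule = FALSE) {
  stopifnot(p_threshold > 0, p_threshold < 1, max_keep >= 1)
  structure(list(p_threshold = p_threshold, max_keep = as.integer(max_keep),
                 family_rule = family_rule), class = "filter_policy")
}

.is_sub_super <- function(a, b) {
  # subset-superset relation between two patterns
  la <- pattern_length(a)
  lb <- pattern_length(b)
  s <- pattern_overlap(a, b)
  pattern_length(s) == min(la, lb)
}

#' Apply a filtering policy to scored meta-chromosomes
#'
#' @param patterns List of [hap_pattern()] objects.
#' @param stats Data frame aligned with `patterns`, columns `fisher_p`,
#'   `case_carrier`, `control_carrier` (chromosome counts in the relevant
#'   universe; identical counts imply identical crude odds ratio).
#' @param policy A [filter_policy()].
#' @return Logical keep-vector over `patterns`.
#' @export
filter_meta_chromosomes <- function(patterns, stats, policy) {
  stopifnot(nrow(stats) == length(patterns))
  n_alleles <- vapply(patterns, pattern_length, integer(1))
  keys <- vapply(patterns, pattern_key, character(1))
  keep <- stats$fisher_p < policy$p_threshold
  if (sum(keep) > policy$max_keep) {
    o <- order(stats$fisher_p, n_alleles, keys)
    o <- o[keep[o]][seq_len(policy$max_keep)]
    keep <- seq_along(patterns) %in% o
  }
  if (policy$family_rule && sum(keep) > 1) {
    idx <- which(keep)
    fam <- paste(stats$case_carrier[idx], stats$control_carrier[idx])
    for (f in unique(fam[duplicated(fam)])) {
      members <- idx[fam == paste(f)]
      if (length(members) < 2) next
      o <- order(n_alleles[members], keys[members])
      anchor <- members[o[1]]
      for (x in setdiff(members, anchor)) {
        related <- any(vapply(setdiff(members, x), function(y) {
          .is_sub_super(patterns[[x]], patterns[[y]])
        }, logical(1)))
        if (!related) keep[x] <- FALSE
      }
    }
  }
  keep
}

#' Phase configuration
#'
#' Tunable thresholds of a discovery phase.  The iteration-1 threshold and
#' the candidate threshold are tuned per locus in practice (so that the
#' retained counts stay near `max_keep` and the regression queue stays
#' tractable); the selection threshold `entry_p` and replication threshold
#' are fixed study-wide.
#'
#' @param max_snps SNP cap for the analysis region (60 for marginal
#'   discovery; 100-200 for conditional discovery in an extended region).
#' @param p_threshold,max_keep,family_rule Iteration-1 filter, see
#'   [filter_policy()].
#' @param candidate_p Fisher cutoff for admission to regression evaluation.
#' @param entry_p LRT threshold for selection/reporting (default 1e-5).
#' @param replication_p Replication threshold (default 0.05).
#' @param max_candidates Cap on the regression queue (smallest p first).
#' @param stepwise_max Cap on the stepwise-selection pool (smallest LRT p
#'   first) once candidates have been reported.
#' @param max_iterations Mining iteration cap.
#' @export
phase_config <- function(max_snps = 60L, p_threshold = 1e-4,
                         max_keep = 100L, family_rule = FALSE,
                         candidate_p = 1e-8, entry_p = 1e-5,
                         replication_p = 0.05, max_candidates = 300L,
                         stepwise_max = 20L, max_iterations = 25L) {
  stopifnot(p_threshold > 0, p_threshold < 1, candidate_p > 0,
            entry_p > 0, entry_p < 1)
  structure(list(max_snps = as.integer(max_snps), p_threshold = p_threshold,
                 max_keep = as.integer(max_keep), family_rule = family_rule,
                 candidate_p = candidate_p, entry_p = entry_p,
                 replication_p = replication_p,
                 max_candidates = as.integer(max_candidates),
                 stepwise_max = as.integer(stepwise_max),
                 max_iterations = as.integer(max_iterations)),
            class = "phase_config")
}

# reuse iteration-1 scores computed inside the mining filter; score only
# patterns not seen there (later iterations and contiguous seeds)
.cached_stats <- function(pats, cache, matrix, subjects, universe = NULL) {
  keys <- vapply(pats, pattern_key, character(1))
  st1 <- cache$st1
  if (is.null(st1)) return(.bulk_pattern_stats(pats, matrix, subjects,
                                               universe))
  hit <- match(keys, st1$key)
  out <- st1[ifelse(is.na(hit), 1L, hit), , drop = FALSE]
  missing <- which(is.na(hit))
  if (length(missing)) {
    out[missing, ] <- .bulk_pattern_stats(pats[missing], matrix, subjects,
                                          universe)
  }
  rownames(out) <- NULL
  out
}

# Collapse candidate patterns to one representative per carrier chromosome
# set -- the closure of that set in the full matrix.  Mined patterns are
# closed with respect to the case seeds but not the whole cohort, so many
# variants tag one and the same chromosome set; association comparisons are
# made on the closures, each distinct carrier set tested once.
.closure_dedup <- function(patterns, matrix, rows = NULL) {
  X <- matrix$alleles
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  keys <- do.call(paste0, as.data.frame(X))
  first <- !duplicated(keys)
  U <- X[first, , drop = FALSE]
  P <- t(vapply(patterns, function(p) pattern_to_dense(p, ncol(X)),
                integer(ncol(X))))
  carries <- matrix(FALSE, length(patterns), nrow(U))
  chunk <- max(512L, floor(2e7 / nrow(U)))
  for (s in seq(1L, nrow(P), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(P))
    Pc <- P[s:e, , drop = FALSE]
    P1 <- (!is.na(Pc) & Pc == 1L) + 0
    P0 <- (!is.na(Pc) & Pc == 0L) + 0
    carries[s:e, ] <- (tcrossprod(P1, U) == rowSums(P1)) &
      (tcrossprod(P0, 1 - U) == rowSums(P0))
  }
  fp <- do.call(paste0, as.data.frame(carries))
  grp <- match(fp, fp[!duplicated(fp)])
  reps <- which(!duplicated(fp))
  closures <- lapply(reps, function(i) {
    rows <- which(carries[i, ])
    v <- U[rows[1], ]
    for (r in rows[-1]) {
      w <- U[r, ]
      v[!is.na(v) & v != w] <- NA_integer_
    }
    dense_to_pattern(v)
  })
  list(closures = closures, group = grp, representative = reps)
}

# carrier chromosome counts + Fisher p for many patterns at once, over the
# chromosome universe selected by `universe` (logical over rows)
.bulk_pattern_stats <- function(patterns, matrix, subjects,
                                universe = NULL) {
  X <- matrix$alleles
  is_case <- subjects$case_status[match(matrix$subject_ids,
                                        subjects$subject_id)]
  if (is.null(universe)) universe <- rep(TRUE, nrow(X))
  Xu <- X[universe, , drop = FALSE]
  cs <- is_case[universe]
  keys <- do.call(paste0, as.data.frame(Xu))
  first <- !duplicated(keys)
  U <- Xu[first, , drop = FALSE]
  grp <- match(keys, keys[first])
  w_case <- tabulate(grp[cs], nbins = sum(first))
  w_ctrl <- tabulate(grp[!cs], nbins = sum(first))
  P <- t(vapply(patterns, function(p) pattern_to_dense(p, ncol(X)),
                integer(ncol(X))))
  counts <- .pattern_support_bulk(P, U, list(case = w_case, ctrl = w_ctrl))
  data.frame(
    key = vapply(patterns, pattern_key, character(1)),
    case_carrier = counts[, 1],
    control_carrier = counts[, 2],
    case_total = sum(cs),
    control_total = sum(!cs),
    fisher_p = .fisher_p_screened(counts[, 1], sum(cs),
                                  counts[, 2], sum(!cs)),
    stringsAsFactors = FALSE)
}

# exact Fisher p where it can matter, Pearson chi-square elsewhere: tables
# whose (instant, vectorized) chi-square p exceeds `exact_below` are far
# from any filtering threshold, so the approximation only has to separate
# "clearly weak" from "worth computing exactly"
.fisher_p_screened <- function(a, n1, b, n0, exact_below = 0.2) {
  N <- n1 + n0
  K <- a + b
  e11 <- K * n1 / N
  chi <- (a - e11)^2 * N^3 /
    pmax(K * (N - K) * as.numeric(n1) * n0, 1)
  p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  need <- which(p < exact_below)
  if (length(need)) {
    p[need] <- fisher_p_vec(a[need], n1, b[need], n0)
  }
  p
}

#' Phase 1: marginal common-haplotype discovery
#'
#' Mines the unique case chromosomes of the (cap-reduced) region, ranks the
#' discovered closed patterns together with the original contiguous
#' haplotypes by marginal Fisher p-value over all chromosomes, evaluates
#' every candidate below `candidate_p` in a Cox dosage model, designates the
#' smallest-LRT-p candidate as the common haplotype, verifies by stepwise
#' forward selection that no second haplotype enters at `entry_p`, and
#' reduces the designated haplotype to its minimal defining allele set
#' (carrier set asserted unchanged).
#'
#' @param matrix A [haplotype_matrix()] for the analysis region.
#' @param subjects A [subject_table()].
#' @param config A [phase_config()].
#' @return List with `h1` (reduced pattern or `NULL` when halted),
#'   `h1_unreduced`, `assoc` (its Cox result), `halted`, `candidates`
#'   (scored table), `iteration_log`, `second_entered`.
#' @export
run_phase1 <- function(matrix, subjects, config = phase_config()) {
  matrix <- reduce_region_symmetric(matrix, config$max_snps)
  is_case <- subjects$case_status[match(matrix$subject_ids,
                                        subjects$subject_id)]
  if (!any(is_case)) stop("no case chromosomes")
  seeds <- seeds_from_matrix(matrix, rows = is_case)
  policy <- filter_policy(config$p_threshold, config$max_keep,
                          config$family_rule)
  cache <- new.env(parent = emptyenv())
  filter_fun <- function(pats, keys) {
    st <- .bulk_pattern_stats(pats, matrix, subjects)
    cache$st1 <- st
    filter_meta_chromosomes(pats, st, policy)
  }
  mined <- mine_closed_patterns(seeds, sigma = 2L, filter_fun = filter_fun,
                                max_iterations = config$max_iterations,
                                m = ncol(matrix$alleles), strategy = "seed")
  cand_idx <- which(mined$discovered$iteration_found >= 1L &
                    mined$discovered$n_alleles >= 1L)
  contiguous <- which(mined$discovered$iteration_found == 0L)
  pats <- mined$patterns[c(cand_idx, contiguous)]
  origin <- rep(c("mined", "contiguous"),
                c(length(cand_idx), length(contiguous)))
  st <- .cached_stats(pats, cache, matrix, subjects)
  st$origin <- origin
  qualifies <- st$fisher_p < config$candidate_p
  report <- list(iteration_log = mined$iteration_log,
                 n_closed = length(cand_idx),
                 n_contiguous = length(contiguous))
  if (!any(qualifies)) {
    return(c(list(h1 = NULL, h1_unreduced = NULL, assoc = NULL,
                  halted = TRUE, candidates = st,
                  second_entered = FALSE), report))
  }
  qual <- which(qualifies)
  dd <- .closure_dedup(pats[qual], matrix)
  cand_pats <- dd$closures
  st <- st[qual[dd$representative], , drop = FALSE]
  st$key <- vapply(cand_pats, pattern_key, character(1))
  rownames(st) <- NULL
  o <- order(st$fisher_p)
  if (length(o) > config$max_candidates) o <- o[seq_len(config$max_candidates)]
  pats <- cand_pats
  copies_list <- lapply(o, function(i) {
    pattern_support(pats[[i]], matrix, subjects)$copies
  })
  fits <- .cox_lrt_batch(copies_list, subjects)
  ok <- !vapply(fits, function(x) isTRUE(x$flagged), logical(1))
  if (!any(ok)) {
    return(c(list(h1 = NULL, h1_unreduced = NULL, assoc = NULL, halted = TRUE,
                  candidates = st, second_entered = FALSE), report))
  }
  o <- o[ok]
  copies_list <- copies_list[ok]
  fits <- fits[ok]
  lrt <- vapply(fits, `[[`, numeric(1), "lrt_p")
  b <- which.min(lrt)
  h1_raw <- pats[[o[b]]]
  best_fit <- fits[[b]]
  best_copies <- copies_list[[b]]
  # verification: with h1 in the model, does any other candidate re-enter?
  second <- FALSE
  if (length(o) > 1) {
    pool <- setdiff(order(lrt), b)
    pool <- pool[seq_len(min(length(pool), config$stepwise_max))]
    cand_copies <- copies_list[pool]
    names(cand_copies) <- st$key[o[pool]]
    sel <- stepwise_forward(cand_copies, base = list(best_copies), subjects,
                            entry_p = config$entry_p, model = "cox")
    second <- length(sel) > 0
  }
  h1 <- reduce_pattern(h1_raw, matrix)
  c(list(h1 = h1, h1_unreduced = h1_raw, assoc = best_fit, halted = FALSE,
         candidates = st[o, , drop = FALSE], second_entered = second),
    report)
}

#' Phase 2: conditional rare-subtype discovery
#'
#' Mines the chromosomes that both carry the conditioning haplotype and
#' belong to cases, filters iteration-1 patterns by the conditional Fisher
#' test (restricted to conditioning-haplotype carriers), evaluates
#' candidates below `candidate_p` in a Cox dosage model with the
#' conditioning haplotype as a baseline term, reports those with LRT
#' p < `entry_p`, and reduces the report to independent signals by stepwise
#' forward selection.  Each selected pattern is adjoined to the conditioning
#' haplotype for reporting.
#'
#' @param matrix A [haplotype_matrix()] for the extended region (must cover
#'   the conditioning haplotype's SNP columns).
#' @param subjects A [subject_table()].
#' @param h1 The conditioning pattern from phase 1.
#' @param config A [phase_config()] (conditional thresholds).
#' @return List with `selected` (keys in selection order), `reported`
#'   (scored table of LRT-qualifying patterns), `patterns` (named list:
#'   reported patterns), `adjoined` (selected patterns unioned with `h1`),
#'   `iteration_log`, `h1_copies`.
#' @export
run_phase2 <- function(matrix, subjects, h1, config = phase_config(
                         max_snps = 200L, p_threshold = 1e-4,
                         max_keep = 30L, family_rule = TRUE,
                         candidate_p = 1e-4)) {
  matrix <- reduce_region_symmetric(matrix, config$max_snps)
  is_case <- subjects$case_status[match(matrix$subject_ids,
                                        subjects$subject_id)]
  carr1 <- pattern_carriers(h1, matrix)
  if (sum(carr1 & is_case) < 2) {
    stop("fewer than 2 conditioning-haplotype-bearing case chromosomes")
  }
  if (!any(carr1 & !is_case)) {
    stop("no conditioning-haplotype carriers among control chromosomes")
  }
  seeds <- seeds_from_matrix(matrix, rows = carr1 & is_case)
  policy <- filter_policy(config$p_threshold, config$max_keep,
                          config$family_rule)
  cache <- new.env(parent = emptyenv())
  filter_fun <- function(pats, keys) {
    st <- .bulk_pattern_stats(pats, matrix, subjects, universe = carr1)
    cache$st1 <- st
    filter_meta_chromosomes(pats, st, policy)
  }
  mined <- mine_closed_patterns(seeds, sigma = 2L, filter_fun = filter_fun,
                                max_iterations = config$max_iterations,
                                m = ncol(matrix$alleles), strategy = "seed")
  cand_idx <- which(mined$discovered$iteration_found >= 1L &
                    mined$discovered$n_alleles >= 1L)
  contiguous <- which(mined$discovered$iteration_found == 0L)
  pats <- mined$patterns[c(cand_idx, contiguous)]
  st <- .cached_stats(pats, cache, matrix, subjects, universe = carr1)
  st$origin <- rep(c("mined", "contiguous"),
                   c(length(cand_idx), length(contiguous)))
  qualifies <- st$fisher_p < config$candidate_p
  if (!any(qualifies)) {
    return(list(selected = character(0),
                reported = cbind(st[0, , drop = FALSE],
                                 effect = numeric(0), lrt_p = numeric(0)),
                patterns = list(), adjoined = list(),
                iteration_log = mined$iteration_log,
                h1_copies = pattern_support(h1, matrix, subjects)$copies))
  }
  qual <- which(qualifies)
  # every conditional pattern contains the conditioning haplotype, so its
  # carriers -- and hence its closure -- live within the h1-carrier rows
  dd <- .closure_dedup(pats[qual], matrix, rows = carr1)
  pats <- dd$closures
  st <- st[qual[dd$representative], , drop = FALSE]
  st$key <- vapply(pats, pattern_key, character(1))
  rownames(st) <- NULL
  h1_copies <- pattern_support(h1, matrix, subjects)$copies
  # rank every distinct carrier set by a fast efficient-score screen, then
  # evaluate the top block exactly by likelihood ratio
  rows_idx <- which(carr1)
  subj_map <- match(matrix$subject_ids, subjects$subject_id)
  Xh <- matrix$alleles[rows_idx, , drop = FALSE]
  n_subj <- nrow(subjects)
  m <- ncol(matrix$alleles)
  scr <- numeric(length(pats))
  carries_all <- matrix(FALSE, length(pats), length(rows_idx))
  chunk <- 400L
  for (s in seq(1L, length(pats), by = chunk)) {
    e <- min(s + chunk - 1L, length(pats))
    P <- t(vapply(pats[s:e], function(p) pattern_to_dense(p, m),
                  integer(m)))
    carries <- .contains_bulk(P, Xh)
    carries_all[s:e, ] <- carries
    D <- matrix(0, n_subj, e - s + 1L)
    for (j in seq_len(nrow(carries))) {
      D[, j] <- tabulate(subj_map[rows_idx[carries[j, ]]], n_subj)
    }
    scr[s:e] <- .score_screen(D, subjects, list(h1_copies))
  }
  o <- order(scr)
  if (length(o) > config$max_candidates) o <- o[seq_len(config$max_candidates)]
  copies_list <- lapply(o, function(i) {
    cp <- tabulate(subj_map[rows_idx[carries_all[i, ]]], n_subj)
    names(cp) <- subjects$subject_id
    cp
  })
  fits <- .cox_lrt_batch(copies_list, subjects,
                         baseline_terms = list(h1_copies))
  rep_ok <- vapply(fits, function(f) {
    !isTRUE(f$flagged) && is.finite(f$lrt_p) && f$lrt_p < config$entry_p
  }, logical(1))
  rep_tab <- st[o[rep_ok], , drop = FALSE]
  rep_tab$effect <- vapply(fits[rep_ok], `[[`, numeric(1), "effect")
  rep_tab$lrt_p <- vapply(fits[rep_ok], `[[`, numeric(1), "lrt_p")
  rep_copies <- copies_list[rep_ok]
  names(rep_copies) <- rep_tab$key
  pool <- order(rep_tab$lrt_p)
  pool <- pool[seq_len(min(length(pool), config$stepwise_max))]
  sel <- stepwise_forward(rep_copies[pool], base = list(h1_copies), subjects,
                          entry_p = config$entry_p, model = "cox")
  rep_pats <- pats[o[rep_ok]]
  names(rep_pats) <- rep_tab$key
  adjoined <- lapply(sel, function(k) pattern_union(rep_pats[[k]], h1))
  names(adjoined) <- sel
  list(selected = sel, reported = rep_tab, patterns = rep_pats,
       adjoined = adjoined, iteration_log = mined$iteration_log,
       h1_copies = h1_copies)
}

#' Replication of candidate patterns in an independent cohort
#'
#' A candidate closed pattern discovered in one population need not be
#' closed in another, so each pattern is evaluated through the chromosomes
#' that carry it there: its SNPs are matched by id into the replication
#' matrix, and when some SNPs are absent the pattern restricted to the
#' shared SNPs is used (equivalently, its closure in the replication data,
#' which has the same carriers).  Association is a logistic dosage model
#' relative to the conditioning-haplotype-alone model; replication requires
#' p below the threshold with a risk-increasing effect.
#'
#' @param patterns Named list of [hap_pattern()] on the discovery index
#'   space.
#' @param discovery_snps The `snps` table of the discovery matrix (for id
#'   matching).
#' @param matrix,subjects Replication cohort.
#' @param h1 Conditioning pattern on the discovery index space, or `NULL`.
#' @param replication_p Threshold (default 0.05).
#' @return Data frame: `key`, `verdict` (`"replicated"`, `"failed"`,
#'   `"untestable"`), `effect`, `p`.
#' @export
replicate_patterns <- function(patterns, discovery_snps, matrix, subjects,
                               h1 = NULL, replication_p = 0.05) {
  remap <- function(p) {
    ids <- discovery_snps$id[p$snp + 1L]
    col <- match(ids, matrix$snps$id)
    ok <- !is.na(col)
    if (!any(ok)) return(NULL)
    hap_pattern(col[ok] - 1L, p$allele[ok])
  }
  base <- list()
  if (!is.null(h1)) {
    h1r <- remap(h1)
    if (is.null(h1r)) stop("conditioning pattern has no SNPs in the ",
                           "replication data")
    base <- list(pattern_support(h1r, matrix, subjects)$copies)
  }
  rows <- lapply(seq_along(patterns), function(k) {
    pr <- remap(patterns[[k]])
    if (is.null(pr)) {
      return(data.frame(key = names(patterns)[k], verdict = "untestable",
                        effect = NA_real_, p = NA_real_))
    }
    cp <- pattern_support(pr, matrix, subjects)$copies
    if (all(cp == 0)) {
      return(data.frame(key = names(patterns)[k], verdict = "untestable",
                        effect = NA_real_, p = NA_real_))
    }
    fit <- logistic_lrt(cp, subjects, baseline_terms = base)
    verdict <- if (isTRUE(fit$flagged)) "untestable"
               else if (is.finite(fit$lrt_p) && fit$lrt_p < replication_p &&
                        fit$effect > 1) "replicated" else "failed"
    data.frame(key = names(patterns)[k], verdict = verdict,
               effect = fit$effect, p = fit$lrt_p)
  })
  do.call(rbind, rows)
}

#' Empirical false-positive replication rate by stratified permutation
#'
#' Permutes case labels among conditioning-haplotype carriers (preserving
#' the observed case heterozygote and homozygote counts, see
#' [permutation_null()]), reruns conditional discovery on the pseudo-case
#' chromosomes of each permutation, and reports the fraction of permuted
#' discoveries (LRT p < `entry_p`, effect > 1) that replicate (p <
#' `replication_p`, effect > 1) in the replication cohort.
#'
#' @param matrix,subjects Discovery cohort (extended region).
#' @param h1 Conditioning pattern.
#' @param config A [phase_config()].
#' @param replication_matrix,replication_subjects Replication cohort.
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @return List with `fraction` (`NA` when no permuted discoveries arise),
#'   `n_discovered`, `n_replicated`, `per_permutation` data frame.
#' @export
estimate_false_positive_rate <- function(matrix, subjects, h1, config,
                                         replication_matrix,
                                         replication_subjects,
                                         n_permutations = 10L, seed = 1L) {
  copies <- pattern_support(h1, matrix, subjects)$copies
  carr <- which(copies > 0)
  carriers <- data.frame(subject_id = subjects$subject_id[carr],
                         case_status = subjects$case_status[carr],
                         copies = copies[carr])
  perms <- permutation_null(carriers, n_permutations, seed)
  n_disc <- integer(n_permutations)
  n_repl <- integer(n_permutations)
  for (j in seq_len(n_permutations)) {
    subj_j <- subjects
    subj_j$case_status[carr] <- perms[, j]
    ph2 <- tryCatch(run_phase2(matrix, subj_j, h1, config),
                    error = function(e) NULL)
    if (is.null(ph2) || !nrow(ph2$reported)) next
    disc <- ph2$reported$effect > 1
    n_disc[j] <- sum(disc)
    if (!any(disc)) next
    verd <- replicate_patterns(ph2$patterns[disc], matrix$snps,
                               replication_matrix, replication_subjects,
                               h1 = h1,
                               replication_p = config$replication_p)
    n_repl[j] <- sum(verd$verdict == "replicated")
  }
  total_disc <- sum(n_disc)
  list(fraction = if (total_disc) sum(n_repl) / total_disc else NA_real_,
       n_discovered = total_disc, n_replicated = sum(n_repl),
       per_permutation = data.frame(permutation = seq_len(n_permutations),
                                    discovered = n_disc,
                                    replicated = n_repl))
}

#' Reduce a haplotype to its minimal defining allele set
#'
#' Grows a full classification tree (no complexity pruning, minimum split
#' size 1, Gini splits, depth at most `max_depth`) predicting
#' carrier-of-`h` from the individual SNP alleles of `h`, and returns the
#' alleles on the path isolating the carrier leaf.  Redundant alleles --
#' those whose value is implied by the rest, e.g. monomorphic columns or
#' alleles in perfect LD with retained ones -- fall away; the carrier
#' chromosome set (hence frequency and effect estimate) is asserted
#' unchanged, with a warning fallback to the original pattern otherwise.
#'
#' @param h A [hap_pattern()] with at least one carrier chromosome.
#' @param matrix A [haplotype_matrix()].
#' @param max_depth Maximum tree depth (default 30).
#' @return A [hap_pattern()] with the same carriers as `h`.
#' @export
reduce_pattern <- function(h, matrix, max_depth = 30L) {
  carr <- pattern_carriers(h, matrix)
  if (!any(carr)) stop("pattern has no carrier chromosomes")
  if (!pattern_length(h)) return(h)
  if (all(carr)) return(hap_pattern())  # carried by everyone: no allele needed
  X <- matrix$alleles[, h$snp + 1L, drop = FALSE]
  colnames(X) <- paste0("s", h$snp)
  df <- data.frame(y = factor(carr, levels = c(FALSE, TRUE)), X,
                   check.names = FALSE)
  fit <- rpart::rpart(y ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        cp = -1, minsplit = 1, minbucket = 1,
                        maxdepth = max_depth, xval = 0,
                        maxcompete = 0, maxsurrogate = 0))
  if (nrow(fit$frame) == 1L) {
    warning("tree grew no splits; returning the original pattern")
    return(h)
  }
  node <- as.integer(rownames(fit$frame))[fit$where[which(carr)[1]]]
  path <- rpart::path.rpart(fit, nodes = node, print.it = FALSE)[[1]][-1]
  var <- sub("[<>=].*$", "", path)
  allele <- ifelse(grepl(">=", path, fixed = TRUE), 1L, 0L)
  snp <- as.integer(sub("^s", "", var))
  # the same variable may appear twice on a path; keep the final constraint
  last <- !duplicated(snp, fromLast = TRUE)
  reduced <- hap_pattern(snp[last], allele[last])
  if (identical(pattern_carriers(reduced, matrix), carr)) reduced
  else {
    warning("reduction altered the carrier set; returning the original")
    h
  }
}
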