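make_seeds <- function(X) {
  lapply(seq_len(nrow(X)), function(r) {
    meta_chromosome(dense_to_pattern(X[r, ]), comprised = r)
  })
}

test_that("the four-chromosome instance yields its six closed patterns", {
  # expected set derived from brute-force all-subset intersections
  X <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 0, 1), c(0, 0, 0))
  expected <- sort(c("0:0,2:1", "1:0,2:1", "0:0,1:0", "2:1", "0:0", "1:0"))
  expect_identical(brute_force_closed_patterns(X, 2), expected)
  for (st in c("pairwise", "seed")) {
    mined <- mine_closed_patterns(make_seeds(X), m = 3, strategy = st)
    expect_identical(sort(mined_closed_set(mined)), expected)
  }
})

test_that("degenerate seed sets terminate immediately", {
  # identical seeds are rejected (uniqueness precondition)
  X <- rbind(c(0, 1), c(0, 1))
  expect_error(mine_closed_patterns(make_seeds(X), m = 2), "unique")
  # two complementary seeds: the single overlap is empty, recorded once
  Xc <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0))
  mined <- mine_closed_patterns(make_seeds(Xc), m = 4)
  expect_true(mined$empty_pattern_seen)
  expect_identical(mined_closed_set(mined), character(0))
  expect_error(mine_closed_patterns(list()), "empty seed")
})

test_that("miner equals the brute-force oracle on random instances", {
  # the acceptance suite runs 200 instances; a fast spot-check here
  expect_identical(oracle_agreement(40, seed = 19), 1)
  # and for the seed-extension strategy
  set.seed(23)
  for (i in 1:25) {
    X <- unique(random_binary_matrix(sample(3:10, 1), sample(4:12, 1)))
    if (nrow(X) < 2) next
    mined <- mine_closed_patterns(make_seeds(X), m = ncol(X),
                                  strategy = "seed")
    expect_identical(sort(mined_closed_set(mined)),
                     brute_force_closed_patterns(X, 2))
  }
})

test_that("sigma-wise overlap generalizes beyond pairs", {
  set.seed(31)
  X <- unique(random_binary_matrix(7, 8))
  mined <- mine_closed_patterns(make_seeds(X), sigma = 3L, m = ncol(X))
  # every pattern shared by >= 3 seeds must be discovered
  expect_true(all(brute_force_closed_patterns(X, 3) %in%
                  mined$discovered$key))
})

test_that("the add-one property holds along the discovery ladder", {
  set.seed(37)
  for (i in 1:10) {
    X <- unique(random_binary_matrix(8, 10))
    if (nrow(X) < 3) next
    mined <- mine_closed_patterns(make_seeds(X), m = ncol(X))
    d <- mined$discovered
    for (k in which(d$iteration_found >= 1 & d$n_alleles >= 1)) {
      comp <- mined$comprised[[k]]
      # extending the comprising set by any one further seed yields a
      # pattern that is itself discovered (possibly empty)
      for (extra in setdiff(seq_len(nrow(X)), comp)) {
        inter <- dense_to_pattern(
          haplomine:::.overlap_fold(X, c(comp, extra)))
        if (pattern_length(inter) >= 1) {
          expect_true(pattern_key(inter) %in% d$key)
        }
      }
    }
  }
})

test_that("discovery grows monotonically and respects the iteration cap", {
  set.seed(41)
  X <- unique(random_binary_matrix(10, 12))
  mined <- mine_closed_patterns(make_seeds(X), m = ncol(X))
  log <- mined$iteration_log
  expect_true(all(log$n_novel[-nrow(log)] > 0))
  # the run ends with no novel pattern, or none worth overlapping further
  expect_lt(log$n_active_next[nrow(log)], 2L)
  expect_error(mine_closed_patterns(make_seeds(X), m = ncol(X),
                                    max_iterations = 1L),
               "did not converge")
})

test_that("overlap never increases support; duplicates are purged", {
  set.seed(43)
  M <- toy_matrix(random_binary_matrix(12, 8))
  X <- unique(M$alleles)
  mined <- mine_closed_patterns(make_seeds(X), m = 8)
  expect_false(anyDuplicated(mined$discovered$key) > 0)
  for (k in seq_along(mined$patterns)[-seq_len(nrow(X))]) {
    h <- mined$patterns[[k]]
    if (!pattern_length(h)) next
    comp <- mined$comprised[[k]]
    carr <- pattern_carriers(h, M)
    # every comprising seed row contains the pattern
    expect_true(all(pattern_contains(X[comp, , drop = FALSE], h)))
  }
})

test_that("the brute-force oracle respects its own contract", {
  X <- rbind(c(0, 1), c(1, 1))
  expect_identical(brute_force_closed_patterns(X[1, , drop = FALSE], 2),
                   character(0))
  # min_support = 1 additionally returns the rows themselves
  with_rows <- brute_force_closed_patterns(X, 1)
  expect_true(all(c("0:0,1:1", "0:1,1:1") %in% with_rows))
  expect_error(brute_force_closed_patterns(random_binary_matrix(40, 30), 2),
               "guard")
})

test_that("the pattern TSV export is stable and complete", {
  X <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 0, 1), c(0, 0, 0))
  mined <- mine_closed_patterns(make_seeds(X), m = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pattern_tsv(mined, toy_snps(3), path)
  tab <- utils::read.delim(path)
  expect_identical(nrow(tab), nrow(mined$discovered))
  expect_true(all(diff(tab$iteration_found) >= 0))
  expect_true(any(grepl("rs3:300:1", tab$entries, fixed = TRUE)))
})
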