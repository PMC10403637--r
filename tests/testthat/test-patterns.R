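test_that("patterns canonicalize and validate their entries", {
  p <- hap_pattern(c(3, 0), c(1, 0))
  expect_identical(p$snp, c(0L, 3L))
  expect_identical(p$allele, c(0L, 1L))
  expect_identical(pattern_key(p), "0:0,3:1")
  expect_identical(pattern_from_key("0:0,3:1")$snp, c(0L, 3L))
  expect_identical(pattern_from_key(""), hap_pattern())
  expect_error(hap_pattern(c(1, 1), c(0, 1)), "duplicate")
  expect_error(hap_pattern(1, 2), "alleles must be 0 or 1")
})

test_that("overlap keeps exactly the shared allele assignments", {
  a <- hap_pattern(0:3, c(0, 1, 0, 1))
  b <- hap_pattern(0:3, c(0, 1, 1, 1))
  expect_identical(pattern_key(pattern_overlap(a, b)), "0:0,1:1,3:1")
  # idempotent, commutative, empty on complementary patterns
  expect_identical(pattern_overlap(a, a), a)
  expect_identical(pattern_overlap(a, b), pattern_overlap(b, a))
  comp <- hap_pattern(0:3, c(1, 0, 1, 0))
  expect_identical(pattern_length(pattern_overlap(a, comp)), 0L)
})

test_that("union adjoins entries and rejects allele conflicts", {
  expect_identical(pattern_union(hap_pattern(0, 1), hap_pattern()),
                   hap_pattern(0, 1))
  u <- pattern_union(hap_pattern(0, 1), hap_pattern(5, 0))
  expect_identical(pattern_key(u), "0:1,5:0")
  expect_error(pattern_union(hap_pattern(0, 1), hap_pattern(0, 0)),
               "conflict")
})

test_that("containment follows the allele-match definition", {
  row <- c(0, 1, 0, 1)
  expect_true(pattern_contains(row, hap_pattern()))
  expect_true(pattern_contains(row, hap_pattern(c(1, 3), c(1, 1))))
  expect_false(pattern_contains(row, hap_pattern(1, 0)))
  M <- rbind(c(0, 1, 0, 1), c(1, 1, 1, 1))
  expect_identical(pattern_contains(M, hap_pattern(0, 0)), c(TRUE, FALSE))
})

test_that("closure is the intersection of the containing chromosomes", {
  M <- toy_matrix(rbind(c(0, 1, 0, 1), c(0, 1, 1, 1)))
  h <- hap_pattern(3, 1)
  cl <- pattern_closure(h, M)
  expect_identical(pattern_key(cl), "0:0,1:1,3:1")
  # fixed point; carriers unchanged
  expect_identical(pattern_closure(cl, M), cl)
  expect_identical(pattern_carriers(cl, M), pattern_carriers(h, M))
  # a uniquely-present full haplotype is its own closure
  M2 <- toy_matrix(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0)))
  full <- dense_to_pattern(c(0L, 1L, 0L, 1L))
  expect_identical(pattern_closure(full, M2), full)
  expect_error(pattern_closure(hap_pattern(c(0, 1), c(1, 1)), M),
               "no chromosome")
})

test_that("closure has the same support as its argument (random instances)", {
  set.seed(11)
  for (i in 1:20) {
    M <- toy_matrix(random_binary_matrix(12, 8))
    k <- sample(8, 2)
    h <- hap_pattern(k - 1L, M$alleles[sample(12, 1), k])
    if (!any(pattern_carriers(h, M))) next
    cl <- pattern_closure(h, M)
    expect_true(all(cl$snp %in% union(h$snp, cl$snp)))
    expect_identical(pattern_carriers(cl, M), pattern_carriers(h, M))
  }
})

test_that("support splits carriers by case status and counts copies", {
  M <- toy_matrix(rbind(c(1, 1), c(1, 1),    # S01 homozygous carrier
                        c(1, 1), c(0, 0),    # S02 heterozygous
                        c(0, 0), c(0, 1)))   # S03 non-carrier
  subj <- toy_subjects(c(TRUE, TRUE, FALSE))
  h <- hap_pattern(c(0, 1), c(1, 1))
  s <- pattern_support(h, M, subj)
  expect_identical(s$case_chrom, 3L)
  expect_identical(s$control_chrom, 0L)
  expect_identical(unname(s$copies), c(2L, 1L, 0L))
  # the empty pattern is carried by every chromosome
  s0 <- pattern_support(hap_pattern(), M, subj)
  expect_identical(s0$case_chrom + s0$control_chrom, 6L)
  expect_true(all(s0$copies == 2L))
  # an absent pattern has zero support everywhere
  sa <- pattern_support(hap_pattern(c(0, 1), c(1, 0)), M, subj)
  expect_identical(c(sa$case_chrom, sa$control_chrom), c(0L, 0L))
  expect_true(all(sa$copies == 0L))
})
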