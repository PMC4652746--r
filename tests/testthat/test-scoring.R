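test_that("base-call probabilities follow the Phred closed forms", {
  expect_equal(base_correct_prob(10), 0.9)
  expect_equal(base_correct_prob(20), 0.99)
  expect_equal(base_correct_prob(0), 0)
  expect_equal(miscall_prob_per_base(0), 1 / 3)
  expect_equal(miscall_prob_per_base(10), 0.1 / 3)
  # three wrong bases plus the correct call always sum to one
  q <- 0:93
  expect_equal(3 * miscall_prob_per_base(q) + base_correct_prob(q),
               rep(1, length(q)))
  expect_error(base_correct_prob(94))
})

test_that("alignment_score matches closed forms and quality monotonicity", {
  sch <- scoring_scheme()
  ref <- "ACGTACGTAC"
  expect_equal(alignment_score(ref, rep(40L, 10), "10M", ref, sch), 20)
  # a low-quality mismatch hurts less than a high-quality one
  mm <- paste0("T", substr(ref, 2, 10))
  s_q40 <- alignment_score(mm, rep(40L, 10), "10M", ref, sch)
  s_q5 <- alignment_score(mm, c(5L, rep(40L, 9)), "10M", ref, sch)
  expect_gt(s_q5, s_q40)
  # affine gap runs and zero-cost soft clips
  expect_equal(alignment_score("ACGTACGTAC", rep(40L, 10), "4M2D6M",
                               "ACGTGGACGTAC", sch),
               20 - (sch$gap_open + sch$gap_extend))
  expect_equal(alignment_score("ACGTACGTAC", rep(40L, 10), "5M5S",
                               "ACGTA", sch), 10)
  expect_error(alignment_score("ACGT", rep(40L, 4), "5M", "ACGTA", sch),
               "inconsistent")
})

test_that("alignment_score is additive over cigar segments", {
  sch <- scoring_scheme()
  set.seed(9)
  for (case in 1:25) {
    L <- sample(20:60, 1)
    ref <- rand_dna(L)
    read <- mutate_subs(ref, sample(L, sample(0:4, 1)))
    q <- sample(2:40, L, replace = TRUE)
    s_whole <- alignment_score(read, q, paste0(L, "M"), ref, sch)
    cut <- sample(2:(L - 2), 1)
    s_parts <- alignment_score(substr(read, 1, cut), q[1:cut],
                               paste0(cut, "M"), substr(ref, 1, cut), sch) +
      alignment_score(substr(read, cut + 1, L), q[(cut + 1):L],
                      paste0(L - cut, "M"), substr(ref, cut + 1, L), sch)
    expect_equal(s_whole, s_parts)
  }
})

test_that("mapQ contract: ties and repeats give 0, caps and monotonicity hold", {
  sch <- scoring_scheme()
  expect_identical(compute_mapq(100, 100, 200), 0L)
  expect_identical(compute_mapq(100, 90, 200, repeat_flag = TRUE), 0L)
  # unique strong hit with no runner-up reaches the cap
  expect_identical(compute_mapq(200, NULL, 200), 60L)
  expect_error(compute_mapq(90, 100, 200), "exceeds")
  # non-increasing in the runner-up score, invariant to common shifts
  sweep <- vapply(seq(0, 100, by = 5), function(s2)
    compute_mapq(100, s2, 200), integer(1))
  expect_true(all(diff(sweep) <= 0))
  expect_identical(compute_mapq(100, 90, 200), compute_mapq(60, 50, 200))
  # always within [0, 60]
  set.seed(10)
  for (i in 1:50) {
    b <- runif(1, 0, 300); s <- runif(1, 0, b)
    mq <- compute_mapq(b, s, 300)
    expect_gte(mq, 0L); expect_lte(mq, 60L)
    expect_identical(mq == 0L, b - s <= 1e-9)
  }
})

test_that("N bases are scored as quality-0 mismatches", {
  sch <- scoring_scheme()
  # read N against a matching-looking reference base still mismatches, at
  # the floor penalty of 2
  expect_equal(alignment_score("NCGT", rep(40L, 4), "4M", "ACGT", sch),
               3 * 2 - 2)
  # reference N can never match either
  expect_equal(alignment_score("ACGT", rep(40L, 4), "4M", "NCGT", sch),
               3 * 2 - 8)
})
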