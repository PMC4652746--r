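test_that("semi-global identity: exact reads score the perfect-match score", {
  set.seed(11)
  win <- rand_dna(200)
  read <- substr(win, 51, 130)
  q <- rep(40L, 80)
  r <- semi_global_one_gap(read, q, win)
  expect_identical(r$cigar, "80M")
  expect_identical(r$ref_start, 50L)
  expect_equal(r$score, max_read_score(read, q))
  expect_error(semi_global_one_gap(rand_dna(50), rep(40L, 50), rand_dna(30)),
               "shorter than read")
})

test_that("semi-global recovers a 2-bp deletion and matches the DP optimum", {
  set.seed(12)
  win <- rand_dna(240)
  span <- substr(win, 81, 157) # 77 ref bases
  read <- paste0(substr(span, 1, 40), substr(span, 43, 77)) # 2 bp deleted
  q <- rep(38L, 75)
  r <- semi_global_one_gap(read, q, win)
  expect_identical(r$cigar, "40M2D35M")
  sch <- scoring_scheme()
  ps <- pbs(read, q, sch)
  dp <- relign:::naive_glocal_dp_cpp(read, ps$mb, ps$mp, win,
                                     sch$gap_open, sch$gap_extend)
  expect_equal(r$score, dp$score)
})

test_that("semi-global equals the one-gap optimum and never beats full DP", {
  set.seed(13)
  sch <- scoring_scheme()
  for (case in 1:60) {
    L <- sample(40:110, 1)
    W <- L + sample(15:70, 1)
    win <- rand_dna(W)
    p0 <- sample(0:(W - L), 1)
    ch <- strsplit(substr(win, p0 + 1, p0 + L), "")[[1]]
    for (i in sample(L, sample(0:5, 1)))
      ch[i] <- sample(c("A", "C", "G", "T"), 1)
    if (runif(1) < 0.6) {
      gl <- sample(1:10, 1); s <- sample(5:(L - 5 - gl), 1)
      if (runif(1) < 0.5) ch <- ch[-(s:(s + gl - 1))]
      else ch <- append(ch, sample(c("A", "C", "G", "T"), gl, TRUE), after = s)
    }
    read <- paste(ch, collapse = "")
    q <- sample(2:40, nchar(read), replace = TRUE)
    ps <- pbs(read, q, sch)
    semi <- semi_global_one_gap(read, q, win, d = 12, scheme = sch)
    one <- relign:::naive_one_gap_cpp(read, ps$mb, ps$mp, win, 12L,
                                      sch$gap_open, sch$gap_extend)
    expect_equal(semi$score, one)
    dp <- relign:::naive_glocal_dp_cpp(read, ps$mb, ps$mp, win,
                                       sch$gap_open, sch$gap_extend)
    expect_lte(semi$score, dp$score + 1e-9)
    if (dp$gap_runs <= 1 && dp$max_run <= 12)
      expect_equal(semi$score, dp$score)
  }
})

test_that("local score closed forms hold", {
  q <- rep(40L, 30)
  s <- strrep("ACGTC", 6)
  expect_equal(sw_score(s, q, s)$score, 60)       # 30 x match bonus 2
  expect_equal(sw_score(strrep("A", 30), q, strrep("C", 40))$score, 0)
})

test_that("banded traceback reproduces the local optimum, growing the band", {
  set.seed(14)
  sch <- scoring_scheme()
  win <- rand_dna(150)
  read <- substr(win, 31, 90)
  q <- rep(40L, nchar(read))
  sw <- sw_score(read, q, win)
  tb <- banded_traceback(read, q, win, sw)
  expect_identical(tb$cigar, "60M")
  expect_equal(tb$score, sw$score)

  # 3-bp insertion; works at band 8, and from band 1 by doubling
  read2 <- paste0(substr(read, 1, 30), "TTT", substr(read, 31, 60))
  q2 <- rep(40L, 63)
  sw2 <- sw_score(read2, q2, win)
  for (b in c(8L, 1L)) {
    tb2 <- banded_traceback(read2, q2, win, sw2, band = b)
    expect_match(tb2$cigar, "3I")
    expect_equal(tb2$score, sw2$score)
    ref_sl <- substr(win, tb2$ref_start + 1, tb2$ref_end)
    expect_equal(alignment_score(read2, q2, tb2$cigar, ref_sl, sch),
                 sw2$score)
  }
})

test_that("local traceback equals full-matrix DP on random pairs", {
  set.seed(15)
  sch <- scoring_scheme()
  for (case in 1:50) {
    L <- sample(25:90, 1)
    win <- rand_dna(L + sample(20:60, 1))
    read <- mutate_subs(substr(win, 11, 10 + L), sample(L, sample(0:6, 1)))
    q <- sample(2:40, L, replace = TRUE)
    ps <- pbs(read, q, sch)
    sw <- sw_score(read, q, win, sch)
    naive <- relign:::naive_local_dp_cpp(read, ps$mb, ps$mp, win,
                                         sch$gap_open, sch$gap_extend)
    expect_equal(sw$score, naive$score)
    if (sw$score > 0) {
      tb <- banded_traceback(read, q, win, sw, scheme = sch)
      expect_identical(unname(cigar_span(tb$cigar)["read"]), L)
      ref_sl <- substr(win, tb$ref_start + 1, tb$ref_end)
      expect_equal(alignment_score(read, q, tb$cigar, ref_sl, sch), sw$score)
    }
  }
})

test_that("the 90% fallback threshold is exact at the boundary", {
  set.seed(16)
  g <- rand_genome(2000)
  idx <- build_index(g)
  read <- substr(g[[1]], 501, 520) # 20 bp, all Q40: max score 40
  # one mismatch at Q10: penalty 2, lost bonus 2 -> score exactly 36 = 0.9 max
  at_thr <- mutate_subs(read, 10)
  q_at <- rep(40L, 20); q_at[10] <- 10L
  st <- relign:::extension_state()
  r1 <- extend_hit(at_thr, q_at, "c1", 500, idx, state = st)
  expect_identical(st$sw_used, 0L)   # not strictly below: no fallback
  expect_equal(r1$score, 36)
  # one mismatch at Q11: penalty 2.2 -> 35.8 < 36 triggers the fallback
  q_below <- q_at; q_below[10] <- 11L
  st2 <- relign:::extension_state()
  r2 <- extend_hit(at_thr, q_below, "c1", 500, idx, state = st2)
  expect_identical(st2$sw_used, 1L)
})

test_that("breakpoint-style reads fall back to clipped local alignment", {
  set.seed(17)
  g <- rand_genome(5000)
  idx <- build_index(g)
  read <- paste0(substr(g[[1]], 1001, 1065), substr(g[[1]], 3001, 3035))
  q <- rep(40L, 100)
  st <- relign:::extension_state()
  r <- extend_hit(read, q, "c1", 1000, idx, state = st)
  expect_identical(r$method, "sw")
  expect_identical(r$cigar, "65M35S")
  expect_identical(r$clip_right, 35L)
})

test_that("the SW budget caps fallback extensions across a read's candidates", {
  set.seed(18)
  g <- rand_genome(4000)
  idx <- build_index(g)
  # a read that always triggers the fallback (right half is foreign)
  read <- paste0(substr(g[[1]], 201, 250), rand_dna(50))
  q <- rep(40L, 100)
  params <- align_params(sw_budget = 8L, stall_limit = 100L)
  st <- relign:::extension_state()
  for (i in 1:20) extend_hit(read, q, "c1", 200 + i, idx, params, state = st)
  expect_lte(st$sw_used, 8L)
  expect_identical(st$sw_used, 8L)
})

test_that("extension scores are self-consistent with the scoring module", {
  set.seed(19)
  sch <- scoring_scheme()
  g <- rand_genome(5000)
  idx <- build_index(g)
  for (case in 1:20) {
    p0 <- sample(4000, 1)
    L <- sample(60:120, 1)
    read <- mutate_subs(substr(g[[1]], p0 + 1, p0 + L),
                        sample(L, sample(0:6, 1)))
    q <- sample(2:40, L, replace = TRUE)
    r <- extend_hit(read, q, "c1", p0, idx, scheme = sch)
    ref_sl <- substr(g[[1]], r$pos + 1,
                     r$pos + unname(cigar_span(r$cigar)["ref"]))
    expect_equal(alignment_score(read, q, r$cigar, ref_sl, sch), r$score)
  }
})
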