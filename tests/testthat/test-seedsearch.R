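test_that("cost steps cover the budget in non-decreasing penalty order", {
  steps <- enumerate_cost_steps(cost_penalties(4, 6, 1), d_seed = 3)
  expect_identical(unlist(steps[1, c("mismatches", "gaps")], use.names = FALSE),
                   c(0L, 0L))
  # mismatch (4) sorts before a length-1 gap (6 + 1)
  r_mm1 <- steps$rank[steps$mismatches == 1 & steps$gaps == 0]
  r_gap1 <- steps$rank[steps$mismatches == 0 & steps$gap_len == 1]
  expect_lt(r_mm1, r_gap1)
  expect_true(all(diff(steps$penalty) >= 0))
  # d_seed = 1: 6 mismatch counts x 2 gap states
  expect_identical(nrow(enumerate_cost_steps(cost_penalties(), d_seed = 1)),
                   12L)
  expect_error(cost_penalties(-1, 6, 1), "positive")
})

test_that("ties order by fewer gaps, then fewer mismatches, then shorter gap", {
  # mismatch 2, open 1, ext 1: (1mm, 0gap) = 2 ties (0mm, gap len1) = 2
  steps <- enumerate_cost_steps(cost_penalties(2, 1, 1), d_seed = 2)
  tied <- steps[abs(steps$penalty - 2) < 1e-12, ]
  expect_identical(tied$gaps, c(0L, 1L))
})

test_that("reverse_align_seed finds least-cost signatures at the origin", {
  set.seed(4)
  g <- rand_genome(4000)
  idx <- build_index(g)
  seed <- substr(g[[1]], 1001, 1075)

  scan <- reverse_align_seed(idx, seed)
  expect_identical(scan$steps[[1]]$step$mismatches, 0L)
  expect_identical(scan$steps[[1]]$hits$pos, 1000)

  seed2 <- mutate_subs(seed, c(10, 40))
  scan2 <- reverse_align_seed(idx, seed2)
  expect_identical(scan2$steps[[1]]$step$mismatches, 2L)
  expect_identical(scan2$steps[[1]]$hits$pos, 1000)

  # seed with 1 bp missing relative to the genome: deletion signature
  seed3 <- paste0(substr(seed, 1, 30), substr(seed, 32, 75),
                  substr(g[[1]], 1076, 1076))
  scan3 <- reverse_align_seed(idx, seed3)
  first <- scan3$steps[[1]]
  expect_identical(first$step$gaps, 1L)
  expect_identical(first$hits$gap_type[1], 1L) # D: reference skips a base

  expect_error(reverse_align_seed(idx, "ACGTACGTACG"), "unseedable")
})

test_that("yielded step penalties are non-decreasing (stream monotonicity)", {
  set.seed(5)
  for (case in 1:10) {
    g <- rand_genome(3000)
    idx <- build_index(g)
    p0 <- sample(1000, 1)
    seed <- mutate_subs(substr(g[[1]], p0, p0 + 74), sample(75, sample(0:5, 1)))
    scan <- reverse_align_seed(idx, seed)
    pens <- vapply(scan$steps, function(s) s$step$penalty, numeric(1))
    expect_true(all(diff(pens) >= 0))
  }
})

test_that("deep_scan branches: multi-hit, unique-hit and lone-hit cases", {
  set.seed(6)
  core <- rand_dna(400)
  # two identical copies -> both returned, no deeper scanning
  g <- genome(c(c1 = paste0(rand_dna(100), core, rand_dna(100), core,
                            rand_dna(100))))
  idx <- build_index(g)
  seed <- substr(core, 51, 125)
  ds <- deep_scan(reverse_align_seed(idx, seed))
  expect_identical(nrow(ds$first), 2L)
  expect_identical(nrow(ds$next_best), 0L)

  # two copies differing by one base: unique least-cost hit at copy A,
  # deep scan surfaces the 1-mismatch hit at copy B
  coreB <- mutate_subs(core, 80)
  g2 <- genome(c(c1 = paste0(rand_dna(100), core, rand_dna(100), coreB,
                             rand_dna(100))))
  idx2 <- build_index(g2)
  ds2 <- deep_scan(reverse_align_seed(idx2, seed))
  expect_identical(nrow(ds2$first), 1L)
  expect_identical(ds2$first$pos, 150)
  expect_identical(ds2$next_best$mismatches, 1L)
  expect_identical(ds2$next_best$pos, 650)

  # lone unique hit with no other placement inside the budget: empty
  # next-best set (mismatch-only budget; with gaps allowed, anchors adjacent
  # to the origin can legitimately re-reach it as gap signatures)
  g3 <- genome(c(c1 = paste0(rand_dna(100), core, rand_dna(100))))
  scan3 <- reverse_align_seed(build_index(g3), seed,
                              budget = list(max_mm = 5L, d_seed = 10L,
                                            allow_gap = FALSE))
  ds3 <- deep_scan(scan3)
  expect_identical(nrow(ds3$first), 1L)
  expect_identical(nrow(ds3$next_best), 0L)
})

test_that("repeat guard trips when a step exceeds the hit ceiling", {
  set.seed(7)
  core <- rand_dna(80)
  g <- genome(c(c1 = paste(c(replicate(5, rand_dna(50)), rep(core, 5)),
                           collapse = "")))
  idx <- build_index(g)
  ds <- deep_scan(reverse_align_seed(idx, substr(core, 1, 75)), max_hits = 3)
  expect_true(ds$repeat_flag)
})

test_that("per-step hit sets equal the brute-force scan on random genomes", {
  set.seed(8)
  for (case in 1:20) {
    g <- rand_genome(sample(1500:3000, 1))
    idx <- build_index(g)
    p0 <- sample(nchar(g[[1]]) - 95, 1)
    seed <- mutate_subs(substr(g[[1]], p0, p0 + 74), sample(75, sample(0:5, 1)))
    if (runif(1) < 0.5) seed <- revcomp(seed)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seed else revcomp(seed)
      imp <- relign:::seed_scan_cpp(relign:::index_ptr(idx), pat, 5L, 10L,
                                    TRUE, 4, 6, 1)
      ora <- relign:::naive_seed_scan_cpp(unname(as.character(g)), pat, 5L,
                                          10L, TRUE, 4, 6, 1)
      expect_identical(hit_key(imp), hit_key(ora))
    }
  }
})
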