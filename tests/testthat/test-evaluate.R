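mk_aln <- function(id, chrom, pos, strand, mapq, mapped = TRUE) {
  a <- alignment_table(length(id))
  a$read_id <- id; a$chrom <- chrom; a$pos <- pos; a$strand <- strand
  a$mapq <- as.integer(mapq); a$mapped <- mapped; a$cigar <- "100M"
  a$seq <- strrep("A", 100); a$qual <- qstr(30, 100)
  a
}

test_that("the 50-bp correctness rule is exact at its boundary", {
  truth <- data.frame(read_id = c("a", "b", "c", "d"), chrom = "c1",
                      pos = 1000, strand = "+")
  aln <- mk_aln(c("a", "b", "c", "d"), "c1", c(1000, 1050, 1051, 1000),
                c("+", "+", "+", "-"), 60)
  expect_identical(is_correct(aln, truth), c(TRUE, TRUE, FALSE, FALSE))
  expect_error(is_correct(mk_aln("zz", "c1", 1, "+", 60), truth), "truth")
})

test_that("mapQ-stratified ROC matches a hand-computed fixture", {
  truth <- data.frame(read_id = sprintf("r%02d", 1:12), chrom = "c1",
                      pos = 100 * (1:12), strand = "+")
  # 10 alignments: mapq 60 (3 correct), 40 (2 correct 1 wrong),
  # 10 (1 correct 1 wrong), 0 (2, discarded); 2 reads unaligned
  aln <- mk_aln(sprintf("r%02d", 1:10), "c1",
                c(100, 200, 300, 400, 500, 9999, 700, 9999, 900, 1000),
                "+", c(60, 60, 60, 40, 40, 40, 10, 10, 0, 0))
  ev <- roc_by_mapq(aln, truth)
  expect_identical(ev$roc$mapq, c(60L, 40L, 10L))
  expect_identical(ev$roc$cum_correct, c(3L, 5L, 6L))
  expect_identical(ev$roc$cum_wrong, c(0L, 1L, 2L))
  # TP = 6, FP = 2, FN = 12 - 8 = 4
  expect_equal(ev$sen, 6 / 10)
  expect_equal(ev$acc, 6 / 8)
  expect_equal(ev$f, f_measure(6 / 10, 6 / 8))
  # every alignment ambiguous: empty ROC, zero sensitivity
  ev0 <- roc_by_mapq(mk_aln("r01", "c1", 100, "+", 0), truth)
  expect_identical(nrow(ev0$roc), 0L)
  expect_equal(ev0$sen, 0)
})

test_that("ROC cumulative coordinates are monotone along decreasing mapQ", {
  set.seed(43)
  truth <- data.frame(read_id = sprintf("r%03d", 1:200), chrom = "c1",
                      pos = 50 * (1:200), strand = "+")
  pos <- ifelse(runif(200) < 0.8, truth$pos, 1e6)
  aln <- mk_aln(truth$read_id, "c1", pos, "+", sample(0:60, 200, TRUE))
  ev <- roc_by_mapq(aln, truth)
  expect_true(all(diff(ev$roc$cum_correct) >= 0))
  expect_true(all(diff(ev$roc$cum_wrong) >= 0))
})

test_that("f_measure follows the harmonic-mean closed form", {
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0.910, 0.99998),
               2 * 0.910 * 0.99998 / (0.910 + 0.99998))
  expect_equal(f_measure(0.7, 0), 0)
  expect_equal(f_measure(0, 0), 0)
  # symmetry and the min-based bound
  set.seed(44)
  for (i in 1:20) {
    a <- runif(1); b <- runif(1)
    expect_equal(f_measure(a, b), f_measure(b, a))
    expect_lte(f_measure(a, b), 2 * min(a, b))
  }
})

test_that("concordance proxy applies the 1000-bp and mapQ>10 rules", {
  a1 <- mk_aln(c("p1/1", "p2/1", "p3/1", "p4/1"), "c1",
               c(1000, 1000, 1000, 1000), "+", c(30, 30, 8, 30))
  a2 <- mk_aln(c("p1/2", "p2/2", "p3/2", "p4/2"), "c1",
               c(1400, 2500, 1200, 1300), "-", c(30, 30, 30, 30))
  a2$mapped[4] <- FALSE
  ce <- concordance_eval(a1, a2)
  # p1 concordant; p2 too far; p3 fails mapQ; p4 excluded (unmapped end)
  expect_identical(ce$concordant, 1L)
  expect_identical(ce$discordant, 2L)
  expect_identical(ce$excluded, 1L)
  expect_identical(ce$by_mapq$mapq_head, c(30L, 8L))
  # wrong orientation (FF) is never concordant
  a2ff <- a2; a2ff$strand <- "+"
  expect_identical(concordance_eval(a1, a2ff)$concordant, 0L)
})
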