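test_that("genome generation is deterministic with realistic composition", {
  g1 <- make_genome(50000, 2, 0, seed = 34)
  g2 <- make_genome(50000, 2, 0, seed = 34)
  expect_identical(as.character(g1), as.character(g2))
  gc <- sum(vapply(strsplit(as.character(g1), ""), function(ch)
    sum(ch %in% c("G", "C")), numeric(1))) / 50000
  expect_lt(abs(gc - 0.41), 0.02)
  expect_error(make_genome(5000, 1, 0, seed = 1))
})

test_that("repeat_fraction places annotated duplications", {
  g <- make_genome(50000, 1, 0.2, seed = 35)
  ann <- attr(g, "repeats")
  expect_gte(sum(ann$len) / 50000, 0.15)
  # annotated copies really are identical in the emitted genome
  for (i in seq_len(min(5, nrow(ann)))) {
    src <- substr(g[[ann$src_chrom[i]]], ann$src_start[i] + 1,
                  ann$src_start[i] + ann$len[i])
    dst <- substr(g[[ann$dst_chrom[i]]], ann$dst_start[i] + 1,
                  ann$dst_start[i] + ann$len[i])
    # later pastes may overwrite earlier ones; require the last one intact
    if (i == nrow(ann)) expect_identical(src, dst)
  }
})

test_that("error-free reads are exact genome substrings at truth positions", {
  g <- make_genome(30000, 2, 0, seed = 36)
  sim <- simulate_reads(g, 100, 80, sub_rate = 0, seed = 36)
  expect_identical(sim$reads$id, sim$truth$read_id) # truth bijection
  for (i in seq_len(50)) {
    tr <- sim$truth[i, ]
    slice <- substr(g[[tr$chrom]], tr$pos + 1, tr$pos + 80)
    want <- if (tr$strand == "-") revcomp(slice) else slice
    expect_identical(sim$reads$seq[i], want)
  }
  expect_true(all(sim$truth$n_mm == 0))
})

test_that("substitution rates track the requested mean within binomial noise", {
  g <- make_genome(30000, 1, 0, seed = 37)
  sim <- simulate_reads(g, 5000, 100, sub_rate = 0.01, seed = 37)
  rate <- sum(sim$truth$n_mm) / (5000 * 100)
  expect_lt(abs(rate - 0.01), 0.002)
  # 7% cap: no read exceeds it
  expect_true(all(sim$truth$n_mm <= 7))
})

test_that("indel spiking modes, rates and bookkeeping are correct", {
  g <- make_genome(40000, 1, 0, seed = 38)
  sim <- simulate_reads(g, 4000, 100, sub_rate = 0, seed = 38)
  same <- spike_indels(sim, g, rate = 0, seed = 38)
  expect_identical(same$reads$seq, sim$reads$seq)

  del <- spike_indels(sim, g, rate = 0.001, mode = "delete", seed = 38)
  specs <- del$truth$indel_spec[del$truth$indel_spec != ""]
  expect_false(any(grepl(":I", specs)))
  n_events <- sum(lengths(strsplit(specs, ";")))
  expect_gt(n_events, 250); expect_lt(n_events, 550) # ~400 expected

  # a spiked deletion is reconstructible from the genome
  i <- which(del$truth$indel_spec != "" & del$truth$strand == "+" &
               !grepl(";", del$truth$indel_spec))[1]
  tr <- del$truth[i, ]
  p <- as.integer(strsplit(tr$indel_spec, ":")[[1]][1:2])
  slice <- substr(g[[tr$chrom]], tr$pos + 1, tr$pos + 100 + p[2])
  want <- paste0(substr(slice, 1, p[1]), substr(slice, p[1] + p[2] + 1,
                                                100 + p[2]))
  expect_identical(del$reads$seq[i], want)
})

test_that("pair simulation honours the insert model and discordant design", {
  g <- make_genome(60000, 2, 0, seed = 39)
  pc <- simulate_pairs(g, 1000, 100, 500, 50, sub_rate = 0, seed = 39)
  t1 <- pc$truth[pc$truth$mate == 1, ]; t2 <- pc$truth[pc$truth$mate == 2, ]
  ins <- (t2$pos + 100) - t1$pos
  expect_lt(abs(mean(ins) - 500), 5)
  expect_true(all(t1$strand == "+" & t2$strand == "-"))
  pd <- simulate_pairs(g, 200, 100, discordant = TRUE, seed = 39)
  d1 <- pd$truth[pd$truth$mate == 1, ]; d2 <- pd$truth[pd$truth$mate == 2, ]
  expect_true(all(d1$chrom != d2$chrom))
  expect_error(simulate_pairs(g, 10, 250, 400, 50, seed = 1), "overlap")
})

test_that("SV rearrangement is reconstructible and bookkeeps breakpoints", {
  g <- make_genome(80000, 2, 0, seed = 40)
  # a single hand-written deletion first: pure arithmetic
  ev <- data.frame(event_id = 1L, type = "deletion", chrom = "chr1",
                   start = 10000, end = 10500, acceptor_chrom = NA,
                   acceptor_pos = NA, src_chrom = NA, src_start = NA,
                   src_end = NA)
  res <- apply_sv_events(g, ev)
  expect_identical(nchar(res$genome[["chr1"]]), nchar(g[["chr1"]]) - 500L)
  expect_identical(res$breakpoints$pos, 10000)

  rg <- rearrange_genome(g, n_events = 20, seed = 40)
  expect_gte(nrow(rg$events), 15)
  re <- apply_sv_events(g, rg$events)
  expect_identical(as.character(re$genome), as.character(rg$genome))
  expect_identical(re$breakpoints, rg$breakpoints)
  # seed-fixed reruns are byte-identical
  rg2 <- rearrange_genome(g, n_events = 20, seed = 40)
  expect_identical(as.character(rg2$genome), as.character(rg$genome))
})

test_that("breakpoint reads straddle junctions with the requested flanks", {
  g <- make_genome(80000, 1, 0, seed = 41)
  rg <- rearrange_genome(g, n_events = 10, seed = 41)
  br <- simulate_breakpoint_reads(rg$genome, rg$breakpoints, 50, 100, 25,
                                  seed = 41)
  expect_identical(nrow(br$reads), 50L)
  off <- br$truth$bp_pos - br$truth$pos
  expect_true(all(off >= 25 & off <= 75))
  # error-free by default: reads are exact rearranged-genome substrings
  i <- which(br$truth$strand == "+")[1]
  expect_identical(br$reads$seq[i],
                   substr(rg$genome[[br$truth$chrom[i]]],
                          br$truth$pos[i] + 1, br$truth$pos[i] + 100))
})

test_that("truth tables round-trip through TSV", {
  g <- make_genome(20000, 1, 0, seed = 42)
  sim <- simulate_reads(g, 20, 75, seed = 42)
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim$truth, fp)
  back <- read_truth(fp)
  expect_identical(back$read_id, sim$truth$read_id)
  expect_equal(back$pos, sim$truth$pos, ignore_attr = TRUE)
})
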