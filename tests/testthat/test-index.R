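test_that("find_exact matches toy genomes, overlaps included", {
  idx <- build_index(genome(c(c1 = "ACGTACGT")))
  expect_identical(find_exact(idx, "ACGT")$pos, c(0, 4))
  expect_identical(find_exact(idx, "TACG")$pos, 3)
  # reverse strand: positions of the reverse complement
  expect_identical(find_exact(idx, "CGTA", strand = "-")$pos, 3)
  idx2 <- build_index(genome(c(c1 = "AAAA")))
  expect_identical(find_exact(idx2, "AA")$pos, c(0, 1, 2))
})

test_that("N never matches, in genome or pattern", {
  idx <- build_index(genome(c(c1 = "ACGNACG")))
  expect_identical(nrow(find_exact(idx, "GNA")), 0L)
  expect_identical(nrow(find_exact(idx, "CGN")), 0L)
  expect_identical(find_exact(idx, "ACG")$pos, c(0, 4))
  expect_error(build_index(genome(c(c1 = "NNNNNNNN"))), "all N")
})

test_that("find_k_mismatch returns exact Hamming neighbourhoods", {
  idx <- build_index(genome(c(c1 = "ACGTACGT")))
  r <- find_k_mismatch(idx, "ACGA", 1)
  expect_identical(r$pos, c(0, 4))
  expect_identical(r$mismatches, c(1L, 1L))
  # k = 0 reduces to find_exact
  r0 <- find_k_mismatch(idx, "ACGT", 0)
  expect_identical(r0$pos, find_exact(idx, "ACGT")$pos)
  expect_true(all(r0$mismatches == 0L))
})

test_that("k-mismatch search is complete and sound vs brute-force scan", {
  set.seed(1)
  for (case in 1:200) {
    nchr <- sample(1:2, 1)
    seqs <- stats::setNames(
      vapply(seq_len(nchr), function(i) rand_dna(sample(300:2000, 1)), ""),
      paste0("c", seq_len(nchr)))
    g <- genome(seqs)
    idx <- build_index(g)
    k <- sample(0:5, 1)
    plen <- sample((2 * max(k, 1)):60, 1)
    strand <- sample(c("+", "-"), 1)
    # half the cases use a genuine (mutated) substring so hits exist
    if (runif(1) < 0.5) {
      cc <- sample(names(g), 1)
      p0 <- sample.int(nchar(g[[cc]]) - plen, 1)
      pat <- substr(g[[cc]], p0, p0 + plen - 1)
      if (k > 0) pat <- mutate_subs(pat, sample(plen, sample(0:k, 1)))
      if (strand == "-") pat <- revcomp(pat)
    } else pat <- rand_dna(plen)
    got <- find_k_mismatch(idx, pat, k, strand)
    qp <- if (strand == "-") revcomp(pat) else pat
    want <- relign:::naive_hamming_cpp(unname(as.character(g)), qp, k)
    expect_identical(paste(got$chrom, got$pos, got$mismatches),
                     paste(names(g)[want$chrom_idx], want$pos,
                           want$mismatches))
  }
})

test_that("reverse-strand hits equal forward hits of the reverse complement", {
  set.seed(2)
  g <- rand_genome(3000)
  idx <- build_index(g)
  for (i in 1:20) {
    pat <- rand_dna(15)
    expect_identical(find_exact(idx, pat, "-"),
                     find_exact(idx, revcomp(pat), "+"))
  }
})

test_that("index files carry a version header and reload equivalently", {
  set.seed(3)
  g <- rand_genome(2000)
  idx <- build_index(g)
  fp <- withr::local_tempfile(fileext = ".idx")
  save_index(idx, fp)
  idx2 <- load_index(fp)
  pat <- substr(g[[1]], 101, 125)
  expect_identical(find_exact(idx2, pat), find_exact(idx, pat))
  saveRDS(list(format = "something-else"), fp)
  expect_error(load_index(fp), "not a relign index")
})
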