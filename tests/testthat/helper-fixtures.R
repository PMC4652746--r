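# shared fixture builders; all randomness is seeded by the calling test

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute k bases at distinct positions (never to the original base)
mutate_subs <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# uniform quality string
qstr <- function(q, n) strrep(intToUtf8(q + 33L), n)

# canonical key of a seed-hit table for set comparison
hit_key <- function(df) {
  sort(paste(df$chrom_idx, df$pos, df$mismatches, df$gaps, df$gap_len,
             df$gap_type, df$split))
}

# random single-chromosome genome object
rand_genome <- function(n, name = "c1") {
  genome(stats::setNames(rand_dna(n), name))
}

# fraction of read positions covered by the M/I spans of a set of alignment
# rows for one read, in the frame of the first row's orientation
joint_read_coverage <- function(rows) {
  rows <- rows[rows$mapped, , drop = FALSE]
  if (!nrow(rows)) return(0)
  L <- nchar(rows$seq[1])
  covered <- rep(FALSE, L)
  for (r in seq_len(nrow(rows))) {
    iv <- relign:::aligned_read_interval(rows$cigar[r])
    if (rows$strand[r] != rows$strand[1]) iv <- c(L - iv[2], L - iv[1])
    if (iv[2] > iv[1]) covered[(iv[1] + 1):iv[2]] <- TRUE
  }
  mean(covered)
}

# per-base score vectors for direct kernel calls
pbs <- function(seq, quals, scheme = scoring_scheme()) {
  relign:::per_base_scores(seq, quals, scheme)
}
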