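#' Seed segments of a read
#'
#' Reads shorter than 150 bp contribute one seed: their first
#' `min(75, length)` bases.  Reads of at least 150 bp are split into
#' `floor(length / 75)` consecutive non-overlapping 75-bp segments from the
#' 5' end; any remainder shorter than 75 bp is used during extension only,
#' never for seeding.
#'
#' @param read_len read length (>= 12).
#' @param seed_len segment length (default 75).
#' @return data.frame with 0-based `start` and `len` per seed segment.
#' @export
choose_seeds <- function(read_len, seed_len = 75L) {
  stopifnot(read_len >= 12)
  read_len <- as.integer(read_len); seed_len <- as.integer(seed_len)
  if (read_len < 2L * seed_len) {
    data.frame(start = 0L, len = min(seed_len, read_len))
  } else {
    k <- read_len %/% seed_len
    data.frame(start = seed_len * (seq_len(k) - 1L), len = seed_len)
  }
}

# oriented read-start anchor implied by a seed hit: the 0-based reference
# position where base 0 of the oriented (strand-adjusted) read would sit
implied_anchor <- function(hit_pos, strand, seg_start, seg_len, read_len) {
  if (strand == "+") hit_pos - seg_start
  else hit_pos - (read_len - seg_start - seg_len)
}

# orient a read to the strand of a hit
orient <- function(seq, qual, strand) {
  if (strand == "+") list(seq = seq, qual = qual)
  else list(seq = revcomp(seq), qual = intToUtf8(rev(utf8ToInt(qual))))
}

# candidate collection for one seed segment: least-cost hits plus deep-scan
# runner-ups, as (chrom, strand, anchor) triples
segment_candidates <- function(scan, ds, seg_start, seg_len, read_len) {
  hits <- rbind(ds$first, ds$next_best)
  if (is.null(hits) || nrow(hits) == 0) return(NULL)
  anch <- ifelse(hits$strand == "+", hits$pos - seg_start,
                 hits$pos - (read_len - seg_start - seg_len))
  fast_df(list(chrom = hits$chrom, strand = hits$strand, anchor = anch,
               step_rank = hits$step_rank))
}

# drop candidates whose extended interval overlaps a better-scoring kept one
# on the same chromosome and strand (they are the same locus reached through
# different seed signatures)
dedupe_extensions <- function(ext) {
  if (length(ext) <= 1) return(ext)
  score <- vapply(ext, function(e) e$score, numeric(1))
  ord <- order(-score,
               vapply(ext, function(e) e$chrom, character(1)),
               vapply(ext, function(e) e$pos, numeric(1)),
               vapply(ext, function(e) e$strand, character(1)))
  kept <- list()
  for (i in ord) {
    e <- ext[[i]]
    dup <- FALSE
    for (k in kept) {
      if (k$chrom == e$chrom && k$strand == e$strand &&
          min(k$ref_end2, e$ref_end2) - max(k$pos, e$pos) >
            0.5 * min(k$ref_end2 - k$pos, e$ref_end2 - e$pos)) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- e
  }
  kept
}

#' Align one read in single-end mode
#'
#' Short reads: reverse-first seed search plus deep-scan on the first 75 bp,
#' each candidate locus extended to the full read and ranked by quality-aware
#' score.  Long reads (>= 150 bp): every 75-bp segment is seeded
#' independently; when the segment hits are non-repetitive and mutually local
#' the whole read is extended once over that locus, otherwise it is extended
#' at every segment's candidate loci and the best score wins.  Mapping
#' quality comes from the two best full-read scores.
#'
#' @param seq,qual read bases and Phred+33 quality string.
#' @param index a `"genome_index"`.
#' @param params an [align_params()].
#' @param scheme a [scoring_scheme()].
#' @param id read identifier carried through to the candidate set.
#' @return list of class `"candidate_set"`: `id`, `candidates` (list of
#'   extension results, ranked by descending score), `mapq`, `repeat_flag`,
#'   `sw_used`.
#' @export
align_single <- function(seq, qual, index, params = align_params(),
                         scheme = scoring_scheme(), id = "read") {
  L <- nchar(seq)
  empty <- structure(list(id = id, candidates = list(), mapq = 0L,
                          repeat_flag = FALSE, sw_used = 0L),
                     class = "candidate_set")
  if (L < 12 || gsub("N", "", seq) == "") return(empty)
  quals <- qual_ints(qual)
  segs <- choose_seeds(L, params$seed_len)
  repeat_flag <- FALSE
  seg_cands <- vector("list", nrow(segs))
  for (si in seq_len(nrow(segs))) {
    s0 <- segs$start[si]; sl <- segs$len[si]
    seed <- substr(seq, s0 + 1, s0 + sl)
    if (gsub("N", "", seed) == "") next
    mm_budget <- if (sl < 75) max(0L, (5L * sl) %/% 75L) else params$max_mm
    scan <- reverse_align_seed(index, seed,
                               budget = list(max_mm = mm_budget,
                                             d_seed = params$d_seed,
                                             allow_gap = TRUE))
    ds <- deep_scan(scan, depth = params$depth, max_hits = params$max_hits)
    repeat_flag <- repeat_flag || ds$repeat_flag
    seg_cands[[si]] <- segment_candidates(scan, ds, s0, sl, L)
  }
  have <- !vapply(seg_cands, is.null, logical(1))
  if (!any(have) && nrow(segs) == 1) {
    # breakpoint fallback: a rearrangement junction inside the seed breaks
    # the full-length scan, but leaves one half intact -- re-scan the seed as
    # two half-length segments with proportionally scaled mismatch budgets
    sl <- segs$len[1]
    half <- sl %/% 2L
    halves <- data.frame(start = c(0L, half), len = c(half, sl - half))
    seg_cands <- vector("list", nrow(halves))
    for (si in seq_len(nrow(halves))) {
      s0 <- halves$start[si]; hl <- halves$len[si]
      if (hl < 12) next
      seed <- substr(seq, s0 + 1, s0 + hl)
      if (gsub("N", "", seed) == "") next
      scan <- reverse_align_seed(index, seed,
                                 budget = list(max_mm = (5L * hl) %/% 75L,
                                               d_seed = params$d_seed,
                                               allow_gap = TRUE))
      ds <- deep_scan(scan, depth = params$depth, max_hits = params$max_hits)
      repeat_flag <- repeat_flag || ds$repeat_flag
      seg_cands[[si]] <- segment_candidates(scan, ds, s0, hl, L)
    }
    segs <- halves
    have <- !vapply(seg_cands, is.null, logical(1))
  }
  if (!any(have)) return(empty)
  multi <- nrow(segs) > 1
  cand <- NULL
  if (multi) {
    # locality shortcut applies only when every segment's least-cost hit is
    # unique (non-repetitive); a multi-hit step means the segment alone
    # cannot distinguish repeat copies and every locus must be examined
    tops <- lapply(seg_cands[have], function(d) d[1, , drop = FALSE])
    tops <- do.call(rbind, tops)
    uniq <- vapply(seg_cands[have], function(d)
      sum(d$step_rank == d$step_rank[1]) == 1, logical(1))
    local_ok <- all(have) && all(uniq) &&
      length(unique(tops$chrom)) == 1 && length(unique(tops$strand)) == 1 &&
      (max(tops$anchor) - min(tops$anchor)) <= L + params$d &&
      !repeat_flag
    if (local_ok) {
      cand <- tops[1, c("chrom", "strand", "anchor")]
    } else {
      cand <- do.call(rbind, seg_cands[have])[, c("chrom", "strand", "anchor")]
    }
  } else {
    cand <- seg_cands[[1]][, c("chrom", "strand", "anchor")]
  }
  cand <- unique(cand)
  if (nrow(cand) > params$max_candidates)
    cand <- cand[seq_len(params$max_candidates), , drop = FALSE]
  state <- extension_state()
  ext <- list()
  for (i in seq_len(nrow(cand))) {
    o <- orient(seq, qual, cand$strand[i])
    e <- extend_hit(o$seq, qual_ints(o$qual), cand$chrom[i], cand$anchor[i],
                    index, params, scheme, state)
    if (is.null(e)) next
    e$strand <- cand$strand[i]
    e$ref_end2 <- e$pos + (e$ref_end - e$ref_start)
    ext[[length(ext) + 1L]] <- e
  }
  if (length(ext) == 0) return(empty)
  ext <- dedupe_extensions(ext)
  best <- ext[[1]]
  second <- if (length(ext) >= 2) ext[[2]]$score else NULL
  mapq <- compute_mapq(best$score, second, best$max_score,
                       repeat_flag = repeat_flag, scheme = scheme)
  structure(list(id = id, candidates = ext, mapq = mapq,
                 repeat_flag = repeat_flag, sw_used = state$sw_used),
            class = "candidate_set")
}

#' Emit the primary alignment of a ranked candidate set
#'
#' The rank-1 candidate becomes the primary alignment with mapQ computed from
#' the two best scores; ties give mapQ 0 with a deterministic
#' (chrom, pos, strand) tie-break already applied by the ranking.
#'
#' @param cands a `"candidate_set"` from [align_single()].
#' @param seq,qual the original (forward) read bases/qualities.
#' @param paired,mate pairing metadata for the SAM FLAG, if any.
#' @return one-row alignment table (see [write_sam()]); an unmapped row when
#'   the candidate set is empty.
#' @export
rank_and_emit <- function(cands, seq, qual, paired = FALSE, mate = NA_integer_) {
  row <- alignment_table(1)
  row$read_id <- cands$id
  row$seq <- seq; row$qual <- qual
  row$paired <- paired; row$mate <- mate
  if (length(cands$candidates) == 0) {
    row$mapped <- FALSE; row$mapq <- 0L
    row$chrom <- NA_character_; row$strand <- NA_character_
    row$cigar <- NA_character_
    return(row)
  }
  b <- cands$candidates[[1]]
  row$mapped <- TRUE
  row$chrom <- b$chrom; row$pos <- b$pos; row$strand <- b$strand
  row$cigar <- b$cigar; row$score <- b$score; row$mapq <- cands$mapq
  row$method <- b$method
  row
}

# aligned read-frame interval [lo, hi) of a cigar in the oriented read
aligned_read_interval <- function(cigar) {
  ops <- parse_cigar(cigar)
  lead <- if (ops$op[1] == "S") ops$len[1] else 0L
  trail <- if (ops$op[nrow(ops)] == "S") ops$len[nrow(ops)] else 0L
  read_len <- sum(ops$len[ops$op %in% c("M", "I", "S")])
  c(lead, read_len - trail)
}

#' Supplementary realignment of a clipped tail
#'
#' Triggers only when a soft clip exceeds `clip_min` (20 bp).  An exact
#' (0-mismatch) scan of the outermost `clip_scan` (20 bp) of the clipped
#' bases proposes candidate loci on both strands; the read is then locally
#' realigned at each and the best-scoring complementary alignment is
#' returned as a supplementary record, so that primary plus supplementary
#' together represent the full read across the breakpoint.
#'
#' @param primary one-row alignment table (the primary alignment).
#' @param index a `"genome_index"`.
#' @param params an [align_params()].
#' @param scheme a [scoring_scheme()].
#' @return zero- or multi-row alignment table of supplementary records.
#' @export
realign_clip <- function(primary, index, params = align_params(),
                         scheme = scoring_scheme()) {
  out <- alignment_table(0)
  if (!primary$mapped) return(out)
  o <- orient(primary$seq, primary$qual, primary$strand)
  L <- nchar(o$seq)
  iv <- aligned_read_interval(primary$cigar)
  sides <- list()
  if (iv[1] > params$clip_min) sides$left <- c(0L, iv[1])
  if (L - iv[2] > params$clip_min) sides$right <- c(iv[2], L)
  for (side in names(sides)) {
    rg <- sides[[side]]
    probe_start <- if (xor(side == "left", !params$clip_outermost))
      rg[1] else rg[2] - params$clip_scan
    probe <- substr(o$seq, probe_start + 1, probe_start + params$clip_scan)
    if (nchar(probe) < params$clip_scan || grepl("N", probe)) next
    best <- NULL
    for (pstrand in c("+", "-")) {
      hits <- find_exact(index, probe, pstrand)
      if (nrow(hits) > 16) hits <- hits[seq_len(16), , drop = FALSE]
      for (h in seq_len(nrow(hits))) {
        if (pstrand == "+") {
          sseq <- o$seq; squal <- o$qual
          anchor <- hits$pos[h] - probe_start
          sstrand <- primary$strand
        } else {
          sseq <- revcomp(o$seq)
          squal <- intToUtf8(rev(utf8ToInt(o$qual)))
          anchor <- hits$pos[h] - (L - probe_start - params$clip_scan)
          sstrand <- if (primary$strand == "+") "-" else "+"
        }
        win <- chrom_slice(index$genome, hits$chrom[h],
                           anchor - params$d - params$window_slack,
                           anchor + L + params$d + params$window_slack)
        if (nchar(win$seq) < params$clip_scan) next
        sq <- qual_ints(squal)
        end <- sw_score(sseq, sq, win$seq, scheme)
        if (end$score <= 0) next
        tb <- tryCatch(
          banded_traceback(sseq, sq, win$seq, end, params$band,
                           params$band_max, scheme),
          error = function(e) NULL)
        if (is.null(tb)) next
        # complementarity: the supplementary must mostly cover clipped bases
        siv <- aligned_read_interval(tb$cigar)
        if (sstrand != primary$strand) siv <- c(L - siv[2], L - siv[1])
        ol_primary <- max(0, min(siv[2], iv[2]) - max(siv[1], iv[1]))
        new_cov <- (siv[2] - siv[1]) - ol_primary
        if (new_cov < params$clip_scan || ol_primary > 10) next
        cand <- list(score = end$score, cigar = tb$cigar, strand = sstrand,
                     chrom = hits$chrom[h], pos = win$start + tb$ref_start)
        if (is.null(best) || cand$score > best$score) best <- cand
      }
    }
    if (!is.null(best)) {
      row <- primary
      row$is_supplementary <- TRUE
      row$chrom <- best$chrom; row$pos <- best$pos
      # the traceback cigar is already stated in the orientation of the
      # supplementary hit (the read handed to it was flipped when needed)
      row$cigar <- best$cigar
      row$strand <- best$strand
      row$score <- best$score
      row$method <- "sw"
      out <- rbind(out, row)
    }
  }
  out
}

#' Align a read set in single-end mode
#'
#' Runs [align_single()] on every read, emits one primary record per read
#' (unmapped reads get FLAG 4 in SAM) and, when a soft clip exceeds the
#' trigger length, supplementary records via [realign_clip()].
#'
#' @param reads a [read_set()].
#' @param index a `"genome_index"`.
#' @param params an [align_params()].
#' @param scheme a [scoring_scheme()].
#' @param supplementary attempt clip realignment (default `TRUE`).
#' @return alignment table (one primary row per read, plus supplementary
#'   rows), suitable for [write_sam()] and [roc_by_mapq()].
#' @export
align_reads <- function(reads, index, params = align_params(),
                        scheme = scoring_scheme(), supplementary = TRUE) {
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    cs <- align_single(reads$seq[i], reads$qual[i], index, params, scheme,
                       id = reads$id[i])
    prim <- rank_and_emit(cs, reads$seq[i], reads$qual[i])
    out <- prim
    if (supplementary && prim$mapped) {
      iv <- aligned_read_interval(prim$cigar)
      L <- nchar(prim$seq)
      if (iv[1] > params$clip_min || L - iv[2] > params$clip_min) {
        sup <- realign_clip(prim, index, params, scheme)
        if (nrow(sup)) out <- rbind(prim, sup)
      }
    }
    rows[[i]] <- out
  }
  do.call(rbind, rows)
}
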