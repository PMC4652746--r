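#' Insert-size model for paired-end libraries
#'
#' @param mean,sd fragment (outer) insert size mean and standard deviation in
#'   bp; both must be positive.  `sd` is floored at 10 bp to keep degenerate
#'   libraries pairable.
#' @param orientation only `"FR"` (forward/reverse, innie) is supported.
#' @return list of class `"insert_model"` with the concordance window
#'   `mean +/- 4 sd` attached.
#' @export
insert_model <- function(mean, sd, orientation = "FR") {
  stopifnot(mean > 0, sd >= 0, orientation == "FR")
  sd <- max(sd, 10)
  structure(list(mean = mean, sd = sd, orientation = orientation,
                 lo = max(0, mean - 4 * sd), hi = mean + 4 * sd),
            class = "insert_model")
}

#' Estimate the insert-size model from confidently mapped pairs
#'
#' Uses pairs where both ends map with mapQ at or above `min_mapq` on the
#' same chromosome: the model mean is the median observed insert and the sd
#' is `1.4826 * MAD` (floored at 10).  With fewer than `min_pairs` qualifying
#' pairs the nominal CLI values are used instead; if those are absent too,
#' this is a configuration error.
#'
#' @param aln1,aln2 alignment tables of the two ends, row-matched by pair.
#' @param nominal_mean,nominal_sd fallback nominal values (e.g. from the
#'   library prep), or `NULL`.
#' @param min_mapq,min_pairs qualification thresholds.
#' @return an [insert_model()].
#' @export
estimate_insert <- function(aln1, aln2, nominal_mean = NULL, nominal_sd = NULL,
                            min_mapq = 20L, min_pairs = 100L) {
  ok <- aln1$mapped & aln2$mapped & aln1$mapq >= min_mapq &
    aln2$mapq >= min_mapq & aln1$chrom == aln2$chrom
  ok[is.na(ok)] <- FALSE
  ins <- numeric(0)
  if (any(ok)) {
    span1 <- vapply(aln1$cigar[ok], function(cg) cigar_span(cg)["ref"], numeric(1))
    span2 <- vapply(aln2$cigar[ok], function(cg) cigar_span(cg)["ref"], numeric(1))
    lo <- pmin(aln1$pos[ok], aln2$pos[ok])
    hi <- pmax(aln1$pos[ok] + span1, aln2$pos[ok] + span2)
    ins <- hi - lo
  }
  if (length(ins) >= min_pairs) {
    return(insert_model(stats::median(ins), 1.4826 * stats::mad(ins, constant = 1)))
  }
  if (is.null(nominal_mean))
    stop("too few confidently mapped pairs to estimate the insert size and ",
         "no nominal value supplied")
  insert_model(nominal_mean, if (is.null(nominal_sd)) 0.1 * nominal_mean
               else nominal_sd)
}

# reference span interval of an extension/alignment candidate
cand_interval <- function(e) c(e$pos, e$pos + unname(cigar_span(e$cigar)["ref"]))

# FR concordance of two placements under an insert model
is_concordant_pair <- function(a, b, model) {
  if (is.null(a) || is.null(b)) return(FALSE)
  if (a$chrom != b$chrom || a$strand == b$strand) return(FALSE)
  plus <- if (a$strand == "+") a else b
  minus <- if (a$strand == "+") b else a
  if (plus$pos > minus$pos) return(FALSE)
  ia <- cand_interval(a); ib <- cand_interval(b)
  ins <- max(ia[2], ib[2]) - min(ia[1], ib[1])
  ins >= model$lo && ins <= model$hi
}

observed_insert <- function(a, b) {
  if (is.null(a) || is.null(b) || a$chrom != b$chrom) return(NA_real_)
  ia <- cand_interval(a); ib <- cand_interval(b)
  max(ia[2], ib[2]) - min(ia[1], ib[1])
}

#' Select the reported placements of a read pair
#'
#' Both ends are aligned independently first; alignment scores precede
#' mate-pair information.  If both top hits are confident (mapQ >=
#' `conf_mapq`) they are reported as-is whether concordant or discordant --
#' a confident discordant pair is never displaced by a weaker concordant
#' combination.  Otherwise the cross-product of the two candidate sets is
#' searched for the best `score1 + score2 + pairing bonus` combination
#' (bonus = one gap-open unit when the combination is concordant) and the
#' pair-level mapQ is recomputed from the two best combination scores.
#'
#' @param cs1,cs2 `"candidate_set"`s of the two ends ([align_single()]).
#' @param model an [insert_model()].
#' @param params an [align_params()].
#' @param scheme a [scoring_scheme()].
#' @return list with `aln1`, `aln2` (chosen extension results or `NULL`),
#'   `mapq1`, `mapq2`, `state` in
#'   `{concordant, discordant, half_mapped, both_unmapped}`, and
#'   `observed_insert`.
#' @export
pair_and_select <- function(cs1, cs2, model, params = align_params(),
                            scheme = scoring_scheme()) {
  c1 <- cs1$candidates; c2 <- cs2$candidates
  if (length(c1) == 0 && length(c2) == 0)
    return(list(aln1 = NULL, aln2 = NULL, mapq1 = 0L, mapq2 = 0L,
                state = "both_unmapped", observed_insert = NA_real_))
  if (length(c1) == 0 || length(c2) == 0)
    return(list(aln1 = if (length(c1)) c1[[1]] else NULL,
                aln2 = if (length(c2)) c2[[1]] else NULL,
                mapq1 = cs1$mapq, mapq2 = cs2$mapq,
                state = "half_mapped", observed_insert = NA_real_))
  t1 <- c1[[1]]; t2 <- c2[[1]]
  if (cs1$mapq >= params$conf_mapq && cs2$mapq >= params$conf_mapq) {
    st <- if (is_concordant_pair(t1, t2, model)) "concordant" else "discordant"
    return(list(aln1 = t1, aln2 = t2, mapq1 = cs1$mapq, mapq2 = cs2$mapq,
                state = st, observed_insert = observed_insert(t1, t2)))
  }
  bonus <- scheme$gap_open
  best <- NULL; best_s <- -Inf; second_s <- -Inf
  for (i in seq_along(c1)) for (j in seq_along(c2)) {
    conc <- is_concordant_pair(c1[[i]], c2[[j]], model)
    s <- c1[[i]]$score + c2[[j]]$score + if (conc) bonus else 0
    if (s > best_s) {
      second_s <- best_s; best_s <- s; best <- list(i = i, j = j, conc = conc)
    } else if (s > second_s) second_s <- s
  }
  a1 <- c1[[best$i]]; a2 <- c2[[best$j]]
  pair_mapq <- compute_mapq(best_s,
                            if (is.finite(second_s)) second_s else NULL,
                            a1$max_score + a2$max_score + bonus,
                            repeat_flag = cs1$repeat_flag && cs2$repeat_flag,
                            scheme = scheme)
  st <- if (best$conc) "concordant" else "discordant"
  list(aln1 = a1, aln2 = a2, mapq1 = pair_mapq, mapq2 = pair_mapq,
       state = st, observed_insert = observed_insert(a1, a2))
}

#' Rescue an unmapped or unpaired mate near its anchor
#'
#' Applies local affine alignment of the mate over the window
#' `anchor +/- (mean + 4 sd + mate length)` on the strand the FR orientation
#' predicts.  The rescued alignment is accepted only when its score reaches
#' `rescue_frac` of the mate's perfect-match score, and it carries a mapQ no
#' larger than the anchor's.
#'
#' @param anchor chosen extension result of the confidently mapped end.
#' @param anchor_mapq its mapQ.
#' @param mate_seq,mate_qual the mate read (forward orientation).
#' @param index a `"genome_index"`.
#' @param model an [insert_model()].
#' @param params an [align_params()].
#' @param scheme a [scoring_scheme()].
#' @return an extension-result-like list with `mapq` and `rescued = TRUE`,
#'   or `NULL` when the rescue fails the score test.
#' @export
rescue_mate <- function(anchor, anchor_mapq, mate_seq, mate_qual, index,
                        model, params = align_params(),
                        scheme = scoring_scheme()) {
  Lm <- nchar(mate_seq)
  reach <- model$mean + 4 * model$sd + Lm
  ia <- cand_interval(anchor)
  if (anchor$strand == "+") {
    w0 <- ia[1]; w1 <- ia[1] + reach
    mstrand <- "-"
  } else {
    w0 <- ia[2] - reach; w1 <- ia[2]
    mstrand <- "+"
  }
  win <- chrom_slice(index$genome, anchor$chrom, w0, w1)
  if (nchar(win$seq) < 20) return(NULL)
  o <- orient(mate_seq, mate_qual, mstrand)
  oq <- qual_ints(o$qual)
  end <- sw_score(o$seq, oq, win$seq, scheme)
  maxs <- max_read_score(mate_seq, qual_ints(mate_qual), scheme)
  if (end$score < params$rescue_frac * maxs) return(NULL)
  tb <- tryCatch(banded_traceback(o$seq, oq, win$seq, end, params$band,
                                  params$band_max, scheme),
                 error = function(e) NULL)
  if (is.null(tb)) return(NULL)
  mq <- min(anchor_mapq,
            compute_mapq(end$score, NULL, maxs, FALSE, scheme))
  list(cigar = tb$cigar, score = end$score, method = "sw",
       chrom = anchor$chrom, pos = win$start + tb$ref_start,
       strand = mstrand, max_score = maxs, mapq = as.integer(mq),
       rescued = TRUE)
}

# assemble one SAM-ready row from a chosen candidate (or unmapped)
pair_row <- function(id, seq, qual, cand, mapq, mate_no) {
  row <- alignment_table(1)
  row$read_id <- id; row$seq <- seq; row$qual <- qual
  row$paired <- TRUE; row$mate <- mate_no
  if (is.null(cand)) {
    row$mapped <- FALSE; row$mapq <- 0L
    row$chrom <- NA_character_; row$strand <- NA_character_
    row$cigar <- NA_character_
  } else {
    row$mapped <- TRUE
    row$chrom <- cand$chrom; row$pos <- cand$pos; row$strand <- cand$strand
    row$cigar <- cand$cigar; row$score <- cand$score
    row$mapq <- as.integer(mapq); row$method <- cand$method
    row$rescued <- isTRUE(cand$rescued)
  }
  row
}

#' Align paired-end reads
#'
#' Ends are aligned independently ([align_single()]), the insert model is
#' estimated from confident pairs (or taken from the nominal values), pairs
#' are selected with scores preceding mate-pair information
#' ([pair_and_select()]) and missing mates are rescued next to confident
#' anchors ([rescue_mate()]).
#'
#' @param reads1,reads2 [read_set()]s of the two ends, row-matched by pair.
#' @param index a `"genome_index"`.
#' @param params an [align_params()].
#' @param scheme a [scoring_scheme()].
#' @param insert_mean,insert_sd nominal insert model used when estimation
#'   lacks data.
#' @return list with `alignments` (SAM-ready table, two rows per pair with
#'   mate/TLEN fields filled), `states` (per-pair pairing state) and the
#'   fitted `model`.
#' @export
align_pairs <- function(reads1, reads2, index, params = align_params(),
                        scheme = scoring_scheme(), insert_mean = NULL,
                        insert_sd = NULL) {
  stopifnot(nrow(reads1) == nrow(reads2))
  n <- nrow(reads1)
  cs1 <- vector("list", n); cs2 <- vector("list", n)
  for (i in seq_len(n)) {
    cs1[[i]] <- align_single(reads1$seq[i], reads1$qual[i], index, params,
                             scheme, id = reads1$id[i])
    cs2[[i]] <- align_single(reads2$seq[i], reads2$qual[i], index, params,
                             scheme, id = reads2$id[i])
  }
  prim <- function(cs, reads, k)
    do.call(rbind, lapply(seq_len(n), function(i)
      rank_and_emit(cs[[i]], reads$seq[i], reads$qual[i], paired = TRUE,
                    mate = k)))
  a1 <- prim(cs1, reads1, 1L); a2 <- prim(cs2, reads2, 2L)
  model <- estimate_insert(a1, a2, insert_mean, insert_sd)
  states <- character(n)
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    sel <- pair_and_select(cs1[[i]], cs2[[i]], model, params, scheme)
    # mate rescue when one end is missing and the other is confident
    if (sel$state == "half_mapped") {
      anchor_is_1 <- !is.null(sel$aln1)
      anchor <- if (anchor_is_1) sel$aln1 else sel$aln2
      amq <- if (anchor_is_1) sel$mapq1 else sel$mapq2
      if (amq >= params$conf_mapq) {
        mate_reads <- if (anchor_is_1) reads2 else reads1
        r <- rescue_mate(anchor, amq, mate_reads$seq[i], mate_reads$qual[i],
                         index, model, params, scheme)
        if (!is.null(r)) {
          if (anchor_is_1) { sel$aln2 <- r; sel$mapq2 <- r$mapq }
          else { sel$aln1 <- r; sel$mapq1 <- r$mapq }
          sel$state <- if (is_concordant_pair(sel$aln1, sel$aln2, model))
            "rescued_concordant" else "discordant"
          sel$observed_insert <- observed_insert(sel$aln1, sel$aln2)
        }
      }
    }
    states[i] <- sel$state
    r1 <- pair_row(reads1$id[i], reads1$seq[i], reads1$qual[i], sel$aln1,
                   sel$mapq1, 1L)
    r2 <- pair_row(reads2$id[i], reads2$seq[i], reads2$qual[i], sel$aln2,
                   sel$mapq2, 2L)
    proper <- sel$state %in% c("concordant", "rescued_concordant")
    r1$proper <- r2$proper <- proper
    r1$mate_mapped <- r2$mapped; r2$mate_mapped <- r1$mapped
    r1$mate_chrom <- r2$chrom; r2$mate_chrom <- r1$chrom
    r1$mate_pos <- r2$pos; r2$mate_pos <- r1$pos
    r1$mate_strand <- r2$strand; r2$mate_strand <- r1$strand
    if (r1$mapped && r2$mapped && !is.na(sel$observed_insert) &&
        identical(r1$chrom, r2$chrom)) {
      sgn <- if (r1$pos <= r2$pos) 1 else -1
      r1$tlen <- sgn * sel$observed_insert
      r2$tlen <- -sgn * sel$observed_insert
    }
    rows[[2 * i - 1]] <- r1; rows[[2 * i]] <- r2
  }
  list(alignments = do.call(rbind, rows), states = states, model = model)
}
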