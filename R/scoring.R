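#' Probability that a base call is correct
#'
#' For Phred score `Q`, the correct-call probability is
#' `P = 1 - 10^(-Q/10)`.
#'
#' @param q integer Phred score(s) in `[0, 93]`.
#' @return probability vector.
#' @export
base_correct_prob <- function(q) {
  stopifnot(all(q >= 0 & q <= 93))
  1 - 10^(-q / 10)
}

#' Probability of one specific miscalled nucleotide
#'
#' Assuming no bias towards any nucleotide, each of the three wrong bases is
#' equally likely, so the per-base miscall probability is `(1 - P) / 3`.
#'
#' @inheritParams base_correct_prob
#' @return probability vector.
#' @export
miscall_prob_per_base <- function(q) (1 - base_correct_prob(q)) / 3

#' Quality-aware affine scoring scheme
#'
#' The per-base match bonus and mismatch penalty are Phred-derived: a mismatch
#' at a confident base costs more than at a doubtful one, so a low-quality
#' mismatch perturbs the alignment score less.  Constants:
#' match bonus 2 for `Q >= 10` else 1; mismatch penalty
#' `max(2, min(Q, q_cap)/5)` (about 2-8); affine gaps cost
#' `gap_open + (L-1) * gap_extend` per run.  `N` bases (read or reference)
#' never match and are penalized as quality-0 mismatches.
#'
#' @param gap_open,gap_extend positive affine gap costs, `gap_open >= gap_extend`.
#' @param q_cap quality ceiling for the mismatch penalty.
#' @param mapq_scale mapQ units per score-unit separation of the two best hits.
#' @param mapq_max mapQ cap.
#' @param floor_frac fraction of the perfect-match score used as the reference
#'   point when no runner-up hit exists.
#' @return object of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(gap_open = 12, gap_extend = 2, q_cap = 40,
                           mapq_scale = 2, mapq_max = 60L, floor_frac = 0.5) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0)
  q <- 0:93
  structure(list(
    match_bonus_by_q = ifelse(q >= 10, 2, 1),
    mismatch_penalty_by_q = pmax(2, pmin(q, q_cap) / 5),
    gap_open = gap_open, gap_extend = gap_extend, q_cap = q_cap,
    mapq_scale = mapq_scale, mapq_max = as.integer(mapq_max),
    floor_frac = floor_frac), class = "scoring_scheme")
}

# per-base match bonus / mismatch penalty vectors for one read; an N base is
# treated as a quality-0 call (penalty 2, and it can never match anyway)
per_base_scores <- function(seq, quals, scheme) {
  q <- pmin(pmax(quals, 0L), 93L)
  isn <- strsplit(seq, "")[[1]] == "N"
  q[isn] <- 0L
  list(mb = scheme$match_bonus_by_q[q + 1L],
       mp = scheme$mismatch_penalty_by_q[q + 1L])
}

#' Perfect-match ("maximum") score of a read
#'
#' The score the read would attain if every base matched; the 90 percent
#' fallback rule and the no-runner-up mapQ floor are both expressed against
#' this quantity.
#'
#' @param seq,quals read bases and integer Phred scores.
#' @param scheme a [scoring_scheme()].
#' @return numeric score.
#' @export
max_read_score <- function(seq, quals, scheme = scoring_scheme()) {
  sum(per_base_scores(seq, quals, scheme)$mb)
}

#' Quality-aware affine alignment score of a placed read
#'
#' Sums match bonuses and mismatch penalties over `M` columns, charges
#' `gap_open + (L-1) * gap_extend` per gap run (`I` or `D`) and scores soft
#' clips as 0.
#'
#' @param seq,quals read bases and integer Phred scores.
#' @param cigar CIGAR string consistent with the read length.
#' @param ref_slice reference bases spanned by the non-clipped part of the
#'   alignment (length = reference span of the CIGAR).
#' @param scheme a [scoring_scheme()].
#' @return numeric score.
#' @export
alignment_score <- function(seq, quals, cigar, ref_slice,
                            scheme = scoring_scheme()) {
  ops <- parse_cigar(cigar)
  if (sum(ops$len[ops$op %in% c("M", "I", "S")]) != nchar(seq))
    stop("CIGAR inconsistent with read length")
  if (sum(ops$len[ops$op %in% c("M", "D")]) != nchar(ref_slice))
    stop("CIGAR inconsistent with reference slice")
  ps <- per_base_scores(seq, quals, scheme)
  rchar <- strsplit(seq, "")[[1]]
  gchar <- strsplit(toupper(ref_slice), "")[[1]]
  score <- 0; i <- 0L; j <- 0L
  for (k in seq_len(nrow(ops))) {
    L <- ops$len[k]
    switch(ops$op[k],
      M = {
        idx <- seq_len(L)
        match <- rchar[i + idx] == gchar[j + idx] & rchar[i + idx] != "N"
        score <- score + sum(ifelse(match, ps$mb[i + idx], -ps$mp[i + idx]))
        i <- i + L; j <- j + L
      },
      I = { score <- score - (scheme$gap_open + (L - 1) * scheme$gap_extend)
            i <- i + L },
      D = { score <- score - (scheme$gap_open + (L - 1) * scheme$gap_extend)
            j <- j + L },
      S = { i <- i + L })
  }
  score
}

#' Mapping quality from the two best hits
#'
#' Ambiguity maps to 0: a repeat-flagged read or a tie between the two best
#' scores gives mapQ 0.  With a runner-up, mapQ grows with the score
#' separation (`mapq_scale` units each); with no runner-up inside the search
#' budget, the separation is measured against `floor_frac * max_score`.
#' Always clamped to `[0, mapq_max]`.
#'
#' @param best_score score of the best hit.
#' @param second_score score of the runner-up hit, or `NULL`/`NA` if none was
#'   found within the search budget.
#' @param max_score perfect-match score of the read ([max_read_score()]).
#' @param repeat_flag `TRUE` when the seed step yielded more hits than the
#'   repeat guard allows; forces mapQ 0.
#' @param scheme a [scoring_scheme()].
#' @return integer mapQ in `[0, mapq_max]`.
#' @export
compute_mapq <- function(best_score, second_score = NULL, max_score,
                         repeat_flag = FALSE, scheme = scoring_scheme()) {
  if (repeat_flag) return(0L)
  if (is.null(second_score) || is.na(second_score))
    second_score <- scheme$floor_frac * max_score
  else if (second_score > best_score + 1e-9)
    stop("second_score exceeds best_score")
  gap <- best_score - second_score
  if (gap <= 1e-9) return(0L)
  as.integer(max(0L, min(scheme$mapq_max, floor(scheme$mapq_scale * gap))))
}
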