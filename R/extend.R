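#' Aligner parameters
#'
#' Bundles the tunables of seeding, extension and reporting.  `mode` presets
#' mirror the single-end speed modes: `"fast"` and `"turbo"` shrink the seed
#' search budget (and, for turbo, the deep-scan depth) relative to
#' `"default"`.
#'
#' @param seed_len seed length (bp); seeds are consecutive non-overlapping
#'   segments from the 5' end.
#' @param max_mm mismatch budget inside a seed (at most 5).
#' @param d_seed maximum gap length inside a seed (bp).
#' @param depth deep-scan depth: non-empty cost steps taken past the first.
#' @param max_hits repeat guard `H`: a cost step yielding more hits marks the
#'   read ambiguous (mapQ 0).
#' @param d maximum indel length during extension (bp).
#' @param band,band_max banded-traceback half-width and its doubling ceiling.
#' @param sw_budget maximum Smith-Waterman extensions per read.
#' @param stall_limit extensions without best-score improvement before the
#'   remaining candidates are skipped.
#' @param sw_threshold fraction of the perfect-match score below which the
#'   semi-global extension falls back to Smith-Waterman.
#' @param clip_min soft-clip length (bp) that must be exceeded before a
#'   supplementary realignment is attempted.
#' @param clip_scan length of the exact scan probe taken from the clipped
#'   bases.
#' @param clip_outermost take the scan probe from the clipped bases furthest
#'   from the primary alignment (`TRUE`, default) or nearest the breakpoint.
#' @param window_slack extra reference bases on each side of the extension
#'   window beyond `read length + d`.
#' @param max_candidates cap on extended candidates per read.
#' @param conf_mapq mapQ at or above which a single-end placement counts as
#'   confident during pairing.
#' @param rescue_frac fraction of the mate's perfect-match score a rescued
#'   alignment must reach to be accepted.
#' @param mode `"default"`, `"fast"` or `"turbo"`.
#' @return list of class `"align_params"`.
#' @export
align_params <- function(seed_len = 75L, max_mm = 5L, d_seed = 10L,
                         depth = 1L, max_hits = 64L, d = 30L, band = 16L,
                         band_max = 256L, sw_budget = 32L, stall_limit = 8L,
                         sw_threshold = 0.9, clip_min = 20L, clip_scan = 20L,
                         clip_outermost = TRUE, window_slack = 8L,
                         max_candidates = 16L, conf_mapq = 20L,
                         rescue_frac = 0.75,
                         mode = c("default", "fast", "turbo")) {
  mode <- match.arg(mode)
  p <- list(seed_len = seed_len, max_mm = max_mm, d_seed = d_seed,
            depth = depth, max_hits = max_hits, d = d, band = band,
            band_max = band_max, sw_budget = sw_budget,
            stall_limit = stall_limit, sw_threshold = sw_threshold,
            clip_min = clip_min, clip_scan = clip_scan,
            clip_outermost = clip_outermost, window_slack = window_slack,
            max_candidates = max_candidates, conf_mapq = conf_mapq,
            rescue_frac = rescue_frac, mode = mode)
  if (mode == "fast") { p$max_mm <- min(p$max_mm, 4L); p$d_seed <- min(p$d_seed, 8L) }
  if (mode == "turbo") {
    p$max_mm <- min(p$max_mm, 3L); p$d_seed <- min(p$d_seed, 5L); p$depth <- 0L
  }
  structure(p, class = "align_params")
}

# shared extension bookkeeping across one read's candidates
extension_state <- function() {
  e <- new.env(parent = emptyenv())
  e$sw_used <- 0L
  e$stall <- 0L
  e$best_score <- -Inf
  e
}

#' One-gap semi-global extension
#'
#' Best alignment of the whole read against the window containing at most one
#' contiguous gap run of length at most `d`: for every candidate anchor the
#' read is split in two parts, one part is aligned mismatch-only and the
#' other tested `j = 1..d` bases away, in both the insertion and deletion
#' directions.  The score is quality-aware; no read base is clipped.
#'
#' @param seq,quals read bases and Phred scores.
#' @param ref_window reference window (at least as long as the read).
#' @param d maximum gap length.
#' @param scheme a [scoring_scheme()].
#' @return list of class `"extension_result"` with `cigar`, `score`, `method`
#'   (`"semiglobal"`), `ref_start`/`ref_end` (0-based, window coordinates),
#'   `clip_left`, `clip_right`.
#' @export
semi_global_one_gap <- function(seq, quals, ref_window, d = 30L,
                                scheme = scoring_scheme()) {
  if (nchar(ref_window) < nchar(seq)) stop("window shorter than read")
  ps <- per_base_scores(seq, quals, scheme)
  r <- semi_global_cpp(toupper(seq), ps$mb, ps$mp, toupper(ref_window),
                       as.integer(d), scheme$gap_open, scheme$gap_extend)
  L <- nchar(seq)
  ops <- switch(as.character(r$type),
    "0" = data.frame(len = L, op = "M"),
    "1" = data.frame(len = c(r$split, r$g, L - r$split),
                     op = c("M", "D", "M")),
    "2" = data.frame(len = c(r$split, r$g, L - r$split - r$g),
                     op = c("M", "I", "M")))
  cigar <- cigar_string(ops)
  span <- unname(cigar_span(cigar)["ref"])
  structure(list(cigar = cigar, score = r$score, method = "semiglobal",
                 ref_start = r$p, ref_end = r$p + span,
                 clip_left = 0L, clip_right = 0L),
            class = "extension_result")
}

#' Best local affine-gap score and end coordinates
#'
#' Score-only pass of the two-step local aligner (score first, banded
#' traceback second).
#'
#' @inheritParams semi_global_one_gap
#' @return list with `score`, `end_read`, `end_ref` (exclusive, 0-based ends).
#' @export
sw_score <- function(seq, quals, ref_window, scheme = scoring_scheme()) {
  ps <- per_base_scores(seq, quals, scheme)
  sw_score_cpp(toupper(seq), ps$mb, ps$mp, toupper(ref_window),
               scheme$gap_open, scheme$gap_extend)
}

#' Banded traceback for a local alignment end point
#'
#' Runs a banded affine DP restricted to a diagonal band through the end
#' coordinates reported by [sw_score()] and traces the optimal path back.
#' If the banded score falls short of the score-only optimum the band is
#' doubled, up to `band_max`; exceeding `band_max` without agreement is an
#' internal error and the alignment is rejected.
#'
#' @inheritParams semi_global_one_gap
#' @param end list from [sw_score()] (`score`, `end_read`, `end_ref`).
#' @param band starting band half-width.
#' @param band_max doubling ceiling.
#' @return `"extension_result"` with soft clips for the unaligned read ends
#'   (`method = "sw"`).
#' @export
banded_traceback <- function(seq, quals, ref_window, end, band = 16L,
                             band_max = 256L, scheme = scoring_scheme()) {
  ps <- per_base_scores(seq, quals, scheme)
  L <- nchar(seq)
  b <- band
  repeat {
    tb <- banded_traceback_cpp(toupper(seq), ps$mb, ps$mp, toupper(ref_window),
                               end$end_read, end$end_ref, as.integer(b),
                               scheme$gap_open, scheme$gap_extend)
    if (!is.na(tb$score) && abs(tb$score - end$score) < 1e-6) break
    if (b >= band_max)
      stop("internal error: banded traceback disagrees with local score at ",
           "maximum band")
    b <- min(band_max, 2L * b)
  }
  ops <- data.frame(len = c(tb$start_read, tb$len, L - end$end_read),
                    op = c("S", tb$op, "S"), stringsAsFactors = FALSE)
  cigar <- cigar_string(ops)
  structure(list(cigar = cigar, score = end$score, method = "sw",
                 ref_start = tb$start_ref, ref_end = end$end_ref,
                 clip_left = tb$start_read, clip_right = L - end$end_read),
            class = "extension_result")
}

# slice [start, end) of one chromosome, clipped to its bounds
chrom_slice <- function(genome, chrom, start, end) {
  n <- nchar(genome[[chrom]])
  start <- max(0, start); end <- min(n, end)
  list(seq = substr(genome[[chrom]], start + 1, end), start = start)
}

#' Extend one seed hit to a full-read alignment
#'
#' Runs the one-gap semi-global extension over a window around the seed
#' anchor; when its score drops below `sw_threshold` times the perfect-match
#' score, falls back to local Smith-Waterman with banded traceback, turning
#' negative-scoring tails into soft clips.  The fallback honors the per-read
#' `sw_budget` and `stall_limit`, and skips the traceback when the local
#' score cannot beat the current best candidate.
#'
#' @param seq,quals read bases and Phred scores, already oriented to the
#'   strand of the hit (reverse-complemented for `-` hits).
#' @param chrom,anchor seed-derived chromosome and approximate 0-based
#'   position of the oriented read's first base.
#' @param index a `"genome_index"`.
#' @param params an [align_params()].
#' @param scheme a [scoring_scheme()].
#' @param state shared per-read extension bookkeeping (internal).
#' @return `"extension_result"` with genomic `pos` (0-based leftmost) added,
#'   or `NULL` when the window cannot hold the read.
#' @export
extend_hit <- function(seq, quals, chrom, anchor, index,
                       params = align_params(), scheme = scoring_scheme(),
                       state = extension_state()) {
  L <- nchar(seq)
  win <- chrom_slice(index$genome, chrom,
                     anchor - params$d - params$window_slack,
                     anchor + L + params$d + params$window_slack)
  if (nchar(win$seq) < L) return(NULL)
  semi <- semi_global_one_gap(seq, quals, win$seq, params$d, scheme)
  maxs <- max_read_score(seq, quals, scheme)
  res <- semi
  if (semi$score < params$sw_threshold * maxs &&
      state$sw_used < params$sw_budget &&
      state$stall < params$stall_limit) {
    state$sw_used <- state$sw_used + 1L
    end <- sw_score(seq, quals, win$seq, scheme)
    # traceback is skipped only when this candidate falls strictly below the
    # current best (a tie must be kept: it is the ambiguity evidence that
    # forces mapQ to 0)
    if (end$score > semi$score && end$score >= state$best_score) {
      res <- banded_traceback(seq, quals, win$seq, end, params$band,
                              params$band_max, scheme)
    }
  }
  if (res$score > state$best_score + 1e-9) {
    state$best_score <- res$score
    state$stall <- 0L
  } else state$stall <- state$stall + 1L
  res$chrom <- chrom
  res$pos <- win$start + res$ref_start
  res$max_score <- maxs
  res
}
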