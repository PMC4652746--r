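#' Unit penalties driving the cost-step enumeration order
#'
#' These order the scanning steps of the reverse-first seed search; they are
#' deliberately simple unit costs, decoupled from the quality-aware scores
#' used later to rank extended alignments.  The gap term here counts
#' `gap_open + L * gap_extend` for a length-`L` gap.
#'
#' @param mismatch,gap_open,gap_extend positive costs.
#' @return list of class `"cost_penalties"`.
#' @export
cost_penalties <- function(mismatch = 4, gap_open = 6, gap_extend = 1) {
  if (any(c(mismatch, gap_open, gap_extend) <= 0))
    stop("cost penalties must be positive")
  structure(list(mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "cost_penalties")
}

.step_cache <- new.env(parent = emptyenv())

#' Enumerate seed-search cost steps in increasing penalty order
#'
#' Covers every combination of up to five mismatches and at most one gap of
#' length `1..d_seed`, sorted by non-decreasing penalty with a deterministic
#' tie order: fewer gaps first, then fewer mismatches, then shorter gap.
#'
#' @param penalties a [cost_penalties()].
#' @param d_seed maximum gap length allowed inside the seed.
#' @param max_mm maximum mismatches (default 5).
#' @return data.frame with columns `mismatches`, `gaps`, `gap_len`,
#'   `penalty`, `rank`.
#' @export
enumerate_cost_steps <- function(penalties = cost_penalties(), d_seed = 10L,
                                 max_mm = 5L) {
  stopifnot(inherits(penalties, "cost_penalties"), d_seed >= 1)
  key <- paste(penalties$mismatch, penalties$gap_open, penalties$gap_extend,
               d_seed, max_mm)
  cached <- .step_cache[[key]]
  if (!is.null(cached)) return(cached)
  nogap <- data.frame(mismatches = 0:max_mm, gaps = 0L, gap_len = 0L)
  gap <- expand.grid(mismatches = 0:max_mm, gaps = 1L,
                     gap_len = seq_len(d_seed))
  steps <- rbind(nogap, gap)
  steps$penalty <- penalties$mismatch * steps$mismatches +
    ifelse(steps$gaps > 0,
           penalties$gap_open + steps$gap_len * penalties$gap_extend, 0)
  ord <- order(steps$penalty, steps$gaps, steps$mismatches, steps$gap_len)
  steps <- steps[ord, , drop = FALSE]
  steps$rank <- seq_len(nrow(steps))
  rownames(steps) <- NULL
  .step_cache[[key]] <- steps
  steps
}

# order hits within one cost step: forward strand before reverse, then
# ascending (chrom, pos) -- determinism for tie-breaks downstream
order_hits <- function(hits) {
  hits[order(match(hits$strand, c("+", "-")), hits$chrom, hits$pos), ,
       drop = FALSE]
}

#' Reverse-first seed search: hits in increasing alignment-cost order
#'
#' Scans the reference for all placements of the seed within the budget (at
#' most `max_mm` mismatches and one gap of length at most `d_seed`), assigns
#' each position its least-penalty signature, and returns the hits grouped by
#' cost step in enumeration order.  Both strands are searched; the hit set of
#' each yielded step is complete for that exact (mismatch, gap) signature.
#'
#' @param index a `"genome_index"`.
#' @param seed seed sequence (at least 12 bp; typically the first
#'   `min(75, read length)` bases of the read).
#' @param budget list with `max_mm`, `d_seed` and `allow_gap`, the searched
#'   sub-space of the full (5 mismatch, 1 gap) budget.
#' @param penalties a [cost_penalties()] fixing the enumeration order.
#' @return object of class `"seed_scan"`: list with `steps` (ordered list of
#'   `list(step = <row of enumerate_cost_steps>, hits = <data.frame>)`, only
#'   non-empty steps), plus the flat `hits` table and the scan parameters.
#' @export
reverse_align_seed <- function(index, seed,
                               budget = list(max_mm = 5L, d_seed = 10L,
                                             allow_gap = TRUE),
                               penalties = cost_penalties()) {
  if (nchar(seed) < 12) stop("seed shorter than 12 bp is unseedable")
  max_mm <- min(budget$max_mm, 5L)
  d_seed <- budget$d_seed
  allow_gap <- isTRUE(budget$allow_gap)
  hit1 <- seed_scan_cpp(index_ptr(index), toupper(seed), max_mm, d_seed,
                        allow_gap, penalties$mismatch, penalties$gap_open,
                        penalties$gap_extend)
  hit2 <- seed_scan_cpp(index_ptr(index), revcomp(seed), max_mm, d_seed,
                        allow_gap, penalties$mismatch, penalties$gap_open,
                        penalties$gap_extend)
  n1 <- length(hit1$pos); n2 <- length(hit2$pos)
  cc <- function(f) c(hit1[[f]], hit2[[f]])
  steps <- enumerate_cost_steps(penalties, d_seed = max(1L, d_seed),
                                max_mm = max_mm)
  mm <- cc("mismatches"); gp <- cc("gaps"); gl <- cc("gap_len")
  skey <- mm * 10000L + gp * 1000L + gl
  rank <- steps$rank[match(skey, steps$mismatches * 10000L +
                             steps$gaps * 1000L + steps$gap_len)]
  hits <- fast_df(list(
    chrom_idx = cc("chrom_idx"), pos = cc("pos"), mismatches = mm,
    gaps = gp, gap_len = gl, gap_type = cc("gap_type"), split = cc("split"),
    penalty = cc("penalty"),
    strand = rep(c("+", "-"), c(n1, n2)),
    chrom = index$chrom_names[cc("chrom_idx")],
    step_rank = rank))
  ord <- order(rank, rep(c(1L, 2L), c(n1, n2)), hits$chrom, hits$pos)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  out <- lapply(split(seq_len(nrow(hits)), hits$step_rank), function(ii)
    list(step = steps[steps$rank == hits$step_rank[ii[1]], ],
         hits = hits[ii, , drop = FALSE]))
  names(out) <- NULL
  structure(list(steps = out, hits = hits, seed_len = nchar(seed),
                 budget = list(max_mm = max_mm, d_seed = d_seed,
                               allow_gap = allow_gap),
                 penalties = penalties),
            class = "seed_scan")
}

#' Continue scanning past the least-cost hit
#'
#' If the first non-empty cost step holds multiple hits they are returned
#' unchanged (they are already the ambiguity evidence mapQ needs).  If the
#' first hit is unique, scanning continues for `depth` further non-empty cost
#' steps and those hits are returned as the next-best set (possibly empty).
#' A step yielding more than `max_hits` hits trips the repeat guard: its hits
#' are kept but deeper scanning stops and downstream mapQ is forced to 0.
#'
#' Deeper steps are filtered for novelty before they are counted: a hit whose
#' anchor lies within `d_seed` of an already-collected hit on the same
#' chromosome and strand is a shadow -- the same locus re-derived through a
#' costlier (usually gapped) signature, not a next-best alignment -- and a
#' step contributing only shadows does not consume scanning depth.
#'
#' @param scan a `"seed_scan"` from [reverse_align_seed()].
#' @param depth number of additional non-empty cost steps to take past the
#'   first (default 1: enough to supply the runner-up hit that mapping
#'   quality is computed from).
#' @param max_hits repeat guard `H`: per-step hit-count ceiling.
#' @return list with `first` (hits of the least-cost step), `next_best`
#'   (novel hits from deeper steps), `repeat_flag`.
#' @export
deep_scan <- function(scan, depth = 1L, max_hits = 64L) {
  stopifnot(inherits(scan, "seed_scan"))
  if (length(scan$steps) == 0)
    return(list(first = NULL, next_best = NULL, repeat_flag = FALSE))
  first <- scan$steps[[1]]$hits
  if (nrow(first) > max_hits)
    return(list(first = first, next_best = first[0, ], repeat_flag = TRUE))
  if (nrow(first) > 1)
    return(list(first = first, next_best = first[0, ], repeat_flag = FALSE))
  tol <- scan$budget$d_seed
  seen <- first[, c("chrom", "strand", "pos")]
  nb <- first[0, ]
  taken <- 0L
  for (i in seq_along(scan$steps)[-1]) {
    h <- scan$steps[[i]]$hits
    if (nrow(h) == 0) next
    if (nrow(h) > max_hits) {
      nb <- rbind(nb, h)
      return(list(first = first, next_best = nb, repeat_flag = TRUE))
    }
    novel <- vapply(seq_len(nrow(h)), function(r)
      !any(seen$chrom == h$chrom[r] & seen$strand == h$strand[r] &
             abs(seen$pos - h$pos[r]) <= tol), logical(1))
    if (!any(novel)) next # shadow-only step: does not consume depth
    nb <- rbind(nb, h[novel, , drop = FALSE])
    seen <- rbind(seen, h[novel, c("chrom", "strand", "pos"), drop = FALSE])
    taken <- taken + 1L
    if (taken >= depth) break
  }
  list(first = first, next_best = nb, repeat_flag = FALSE)
}
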