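#' Correctness of an alignment against its simulator truth
#'
#' An alignment is correct when it is on the same chromosome and strand as
#' the simulated origin and its leftmost position is within `tol` (50 bp by
#' default) of the simulated position -- the slack absorbs indel placement
#' ambiguity and soft clipping near variant breakpoints.
#'
#' @param alignments alignment table (primaries).
#' @param truth truth table with `read_id`, `chrom`, `pos`, `strand`.
#' @param tol positional tolerance in bp.
#' @return logical vector along `alignments`; errors if a read has no truth
#'   record.
#' @export
is_correct <- function(alignments, truth, tol = 50) {
  m <- match(alignments$read_id, truth$read_id)
  if (anyNA(m)) stop("missing truth record for aligned read")
  alignments$mapped &
    alignments$chrom == truth$chrom[m] &
    alignments$strand == truth$strand[m] &
    abs(alignments$pos - truth$pos[m]) <= tol
}

#' Cumulative correct/wrong counts stratified by mapQ
#'
#' Follows the simulated-data evaluation protocol: mapQ-0 mappings are
#' discarded as ambiguous; the remaining primaries are sorted by decreasing
#' mapQ and cumulative (correct, wrong) counts are recorded at every
#' distinct mapQ value.  At the full-spectrum point, sensitivity is
#' `TP / (TP + FN)` and accuracy (used interchangeably with specificity)
#' `TP / (TP + FP)`, where TP/FP are correct/incorrect mapQ>0 primaries and
#' FN are simulated reads with no mapQ>0 primary.
#'
#' @param alignments alignment table (primary records; supplementary rows
#'   are ignored).
#' @param truth truth table.
#' @param tol positional tolerance for [is_correct()].
#' @return list of class `"eval_summary"`: `roc` (data.frame `mapq`,
#'   `cum_correct`, `cum_wrong`), `sen`, `acc`, `f`, `n_reads`.
#' @export
roc_by_mapq <- function(alignments, truth, tol = 50) {
  prim <- alignments[!alignments$is_supplementary, , drop = FALSE]
  n_reads <- nrow(truth)
  keep <- prim$mapped & prim$mapq > 0
  kept <- prim[keep, , drop = FALSE]
  correct <- if (nrow(kept)) is_correct(kept, truth, tol) else logical(0)
  tp <- sum(correct); fp <- sum(!correct)
  fn <- n_reads - nrow(kept)
  sen <- if (tp + fn > 0) tp / (tp + fn) else 0
  acc <- if (tp + fp > 0) tp / (tp + fp) else 0
  if (nrow(kept)) {
    ord <- order(-kept$mapq)
    mq <- kept$mapq[ord]; cr <- correct[ord]
    uq <- unique(mq)
    cumc <- cumsum(cr); cumw <- cumsum(!cr)
    idx <- vapply(uq, function(q) max(which(mq == q)), integer(1))
    roc <- data.frame(mapq = uq, cum_correct = cumc[idx],
                      cum_wrong = cumw[idx])
  } else {
    roc <- data.frame(mapq = integer(0), cum_correct = integer(0),
                      cum_wrong = integer(0))
  }
  structure(list(roc = roc, sen = sen, acc = acc, f = f_measure(sen, acc),
                 n_reads = n_reads),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("eval_summary: n = %d, SEN = %.4f, ACC = %.5f, F = %.4f\n",
              x$n_reads, x$sen, x$acc, x$f))
  invisible(x)
}

#' F-measure (harmonic mean of sensitivity and accuracy)
#'
#' `F = 2 * SEN * ACC / (SEN + ACC)`, defined as 0 when both are 0.
#'
#' @param sen,acc values in `[0, 1]`.
#' @return F-measure.
#' @export
f_measure <- function(sen, acc) {
  stopifnot(sen >= 0, sen <= 1, acc >= 0, acc <= 1)
  if (sen + acc == 0) return(0)
  2 * sen * acc / (sen + acc)
}

#' Concordance evaluation of single-end-mapped pairs
#'
#' The oracle-free proxy used on real data: paired reads are mapped as
#' single-end reads, and a pair counts as concordant when the ends have
#' correct FR orientation on the same chromosome, map within `max_dist`
#' (1000 bp) of each other and both have mapQ above `min_mapq` (10).
#' Both-mapped pairs failing any clause are discordant; pairs with an
#' unmapped end are excluded.  Counts are stratified by the mapQ of the
#' head read (read 1).
#'
#' @param aln1,aln2 single-end alignment tables of the two ends, row-matched
#'   by pair.
#' @param max_dist maximum distance between leftmost positions.
#' @param min_mapq strict lower bound on both mapQs.
#' @return list with `by_mapq` (data.frame `mapq_head`, `concordant`,
#'   `discordant`, sorted by decreasing head mapQ) and the totals
#'   `concordant`, `discordant`, `excluded`.
#' @export
concordance_eval <- function(aln1, aln2, max_dist = 1000, min_mapq = 10) {
  stopifnot(nrow(aln1) == nrow(aln2))
  both <- aln1$mapped & aln2$mapped
  fr_ok <- rep(FALSE, nrow(aln1))
  idx <- which(both)
  for (i in idx) {
    if (aln1$strand[i] == aln2$strand[i]) next
    plus_pos <- if (aln1$strand[i] == "+") aln1$pos[i] else aln2$pos[i]
    minus_pos <- if (aln1$strand[i] == "-") aln1$pos[i] else aln2$pos[i]
    fr_ok[i] <- plus_pos <= minus_pos
  }
  conc <- both & aln1$chrom == aln2$chrom & fr_ok &
    abs(aln1$pos - aln2$pos) <= max_dist &
    aln1$mapq > min_mapq & aln2$mapq > min_mapq
  conc[is.na(conc)] <- FALSE
  res <- data.frame(mapq_head = aln1$mapq[both],
                    concordant = conc[both])
  agg <- stats::aggregate(concordant ~ mapq_head, data = res,
                          FUN = function(z) c(sum(z), sum(!z)))
  by_mapq <- data.frame(mapq_head = agg$mapq_head,
                        concordant = agg$concordant[, 1],
                        discordant = agg$concordant[, 2])
  by_mapq <- by_mapq[order(-by_mapq$mapq_head), , drop = FALSE]
  rownames(by_mapq) <- NULL
  list(by_mapq = by_mapq, concordant = sum(conc[both]),
       discordant = sum(!conc[both]), excluded = sum(!both))
}
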