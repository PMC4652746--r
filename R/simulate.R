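# Synthetic data generators: random genomes with controllable repeat content,
# Illumina-like reads with a position-dependent quality profile, indel
# spiking, concordant/discordant pairs and SV-rearranged genomes.  Every
# generator takes a mandatory seed and is deterministic under it; internal
# seed offsets keep the per-component RNG streams separate so adding reads
# does not perturb genome generation.

#' Generate a random reference genome
#'
#' Base composition targets GC of about 0.41.  `repeat_fraction` of the
#' sequence is made of duplicated segments (200-1000 bp copies pasted
#' elsewhere), annotated in the `repeats` attribute, to exercise repeat
#' handling and deep scanning.
#'
#' @param length total genome length (>= 10 kb).
#' @param n_chroms number of equally sized chromosomes.
#' @param repeat_fraction fraction of positions inside duplicated segments.
#' @param seed RNG seed (mandatory).
#' @return a [genome()] with a `repeats` annotation attribute.
#' @export
make_genome <- function(length, n_chroms = 1L, repeat_fraction = 0,
                        seed) {
  stopifnot(length >= 10000, n_chroms >= 1)
  set.seed(seed)
  per <- rep(length %/% n_chroms, n_chroms)
  per[n_chroms] <- per[n_chroms] + length - sum(per)
  bases <- c("A", "C", "G", "T")
  prob <- c(0.295, 0.205, 0.205, 0.295)
  seqs <- vapply(per, function(n)
    paste(sample(bases, n, replace = TRUE, prob = prob), collapse = ""),
    character(1))
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  g <- genome(seqs)
  rep_ann <- data.frame(src_chrom = character(0), src_start = numeric(0),
                        dst_chrom = character(0), dst_start = numeric(0),
                        len = numeric(0))
  if (repeat_fraction > 0) {
    placed <- 0
    target <- repeat_fraction * length
    while (placed < target) {
      len <- sample(200:1000, 1)
      sc <- sample(names(g), 1)
      if (nchar(g[[sc]]) < 2 * len + 2) next
      s0 <- sample.int(nchar(g[[sc]]) - len, 1) - 1L
      dc <- sample(names(g), 1)
      d0 <- sample.int(nchar(g[[dc]]) - len, 1) - 1L
      piece <- substr(g[[sc]], s0 + 1, s0 + len)
      gs <- unclass(g)
      substr(gs[[dc]], d0 + 1, d0 + len) <- piece
      g <- genome(gs)
      rep_ann <- rbind(rep_ann, data.frame(
        src_chrom = sc, src_start = s0, dst_chrom = dc, dst_start = d0,
        len = len))
      placed <- placed + len
    }
  }
  attr(g, "repeats") <- rep_ann
  g
}

# position-dependent quality curve: starts near Q38 and decays towards Q25 at
# the end of the read, with logistic shape plus per-base noise
profile_quals <- function(read_len) {
  cyc <- seq_len(read_len)
  mean_q <- 38 - 13 / (1 + exp(-(cyc - 0.6 * read_len) / (0.15 * read_len)))
  q <- round(mean_q + rnorm(read_len, 0, 2))
  pmin(pmax(q, 2L), 40L)
}

# draw quality string + substitution errors for one oriented read sequence;
# substitution probability is quality-conditional (low Q -> more errors) and
# optionally rescaled so the mean per-base rate equals sub_rate
synth_errors <- function(seq, sub_rate, max_error_frac = 0.07) {
  L <- nchar(seq)
  q <- profile_quals(L)
  e <- 10^(-q / 10)
  p <- if (is.null(sub_rate)) e else pmin(0.5, sub_rate * e / mean(e))
  hit <- which(runif(L) < p)
  cap <- floor(max_error_frac * L)
  if (length(hit) > cap) hit <- sort(sample(hit, cap))
  if (length(hit)) {
    ch <- strsplit(seq, "")[[1]]
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    seq <- paste(ch, collapse = "")
  }
  list(seq = seq, qual = intToUtf8(q + 33L), n_mm = length(hit))
}

empty_truth <- function() {
  data.frame(read_id = character(0), class = character(0),
             chrom = character(0), pos = numeric(0), strand = character(0),
             read_len = integer(0), n_mm = integer(0),
             indel_spec = character(0), stringsAsFactors = FALSE)
}

#' Simulate Illumina-like reads with truth records
#'
#' Reads are drawn uniformly from both strands; per-base substitution errors
#' follow the quality profile (low quality implies higher error), optionally
#' rescaled to a target mean rate, and the combined per-read error fraction
#' is capped at 7 percent.  Every read gets a truth record with its 0-based
#' leftmost forward-strand origin.
#'
#' @param genome a [genome()].
#' @param n number of reads.
#' @param read_len read length (75/100/250 typical).
#' @param sub_rate target mean substitution rate, or `NULL` to use the raw
#'   quality-implied rates.
#' @param seed RNG seed.
#' @param class label stored in the truth table.
#' @return list with `reads` (a [read_set()]) and `truth` (data.frame).
#' @export
simulate_reads <- function(genome, n, read_len = 100L, sub_rate = 0.01,
                           seed, class = "illumina") {
  set.seed(seed + 1L)
  clen <- nchar(genome)
  stopifnot(any(clen >= read_len))
  okc <- names(genome)[clen >= read_len]
  w <- clen[okc] - read_len + 1
  chrom <- sample(okc, n, replace = TRUE, prob = w)
  pos <- vapply(chrom, function(cc) sample.int(clen[cc] - read_len + 1L, 1L) - 1L,
                integer(1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ids <- sprintf("%s_%06d", class, seq_len(n))
  seqs <- character(n); quals <- character(n); nmm <- integer(n)
  for (i in seq_len(n)) {
    slice <- substr(genome[[chrom[i]]], pos[i] + 1, pos[i] + read_len)
    oriented <- if (strand[i] == "-") revcomp(slice) else slice
    se <- synth_errors(oriented, sub_rate)
    seqs[i] <- se$seq; quals[i] <- se$qual; nmm[i] <- se$n_mm
  }
  truth <- data.frame(read_id = ids, class = class, chrom = chrom,
                      pos = as.numeric(pos), strand = strand,
                      read_len = read_len, n_mm = nmm, indel_spec = "",
                      stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(reads = read_set(ids, seqs, quals), truth = truth)
}

#' Spike indels into simulated reads
#'
#' Each base independently starts an indel with probability `rate`
#' (default 0.001); lengths are geometric, truncated at 10 bp.  A deletion
#' removes read bases and extends the genomic span to keep the read length
#' fixed; an insertion adds novel bases and trims the span.  Separate
#' insert-only and delete-only modes are available.  The combined 7 percent
#' error cap is enforced; reads that would exceed it are left unspiked.
#'
#' @param sim result of [simulate_reads()].
#' @param genome the [genome()] the reads came from.
#' @param rate per-base indel rate.
#' @param mode `"both"`, `"insert"` or `"delete"`.
#' @param seed RNG seed.
#' @param max_len maximum indel length.
#' @return list with updated `reads` and `truth` (indels recorded as
#'   `offset:len:type` in forward-genome frame, `class = "indel_spiked"`).
#' @export
spike_indels <- function(sim, genome, rate = 0.001, mode = "both", seed,
                         max_len = 10L) {
  stopifnot(mode %in% c("both", "insert", "delete"))
  set.seed(seed + 2L)
  reads <- sim$reads; truth <- sim$truth
  if (rate <= 0) return(sim)
  for (i in seq_len(nrow(reads))) {
    L <- truth$read_len[i]
    k <- rbinom(1, L, rate)
    if (k == 0) next
    f <- if (truth$strand[i] == "-") revcomp(reads$seq[i]) else reads$seq[i]
    span <- L
    specs <- character(0)
    total_indel <- 0L
    for (e in seq_len(k)) {
      g <- min(max_len, rgeom(1, 0.4) + 1L)
      type <- switch(mode, insert = "I", delete = "D",
                     both = sample(c("I", "D"), 1))
      if ((truth$n_mm[i] + total_indel + g) / L > 0.07) next
      o <- sample(5:(L - 5 - g), 1)
      cs <- nchar(genome[[truth$chrom[i]]])
      if (type == "D") {
        if (truth$pos[i] + span + g > cs) next
        ext <- substr(genome[[truth$chrom[i]]], truth$pos[i] + span + 1,
                      truth$pos[i] + span + g)
        f <- paste0(substr(f, 1, o), substr(f, o + g + 1, L), ext)
        span <- span + g
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), g, replace = TRUE),
                     collapse = "")
        f <- paste0(substr(f, 1, o), ins, substr(f, o + 1, L - g))
        span <- span - g
      }
      total_indel <- total_indel + g
      specs <- c(specs, sprintf("%d:%d:%s", o, g, type))
    }
    if (length(specs) == 0) next
    reads$seq[i] <- if (truth$strand[i] == "-") revcomp(f) else f
    truth$indel_spec[i] <- paste(specs, collapse = ";")
    truth$class[i] <- "indel_spiked"
  }
  list(reads = reads, truth = truth)
}

#' Simulate paired-end reads
#'
#' Concordant mode draws FR pairs with fragment (outer insert) size
#' `Normal(mean, sd)` truncated to at least twice the read length;
#' discordant mode draws the left and right ends independently from two
#' different chromosomes.  Both ends carry the same error model as
#' [simulate_reads()].
#'
#' @param genome a [genome()] (discordant mode needs at least 2 chromosomes).
#' @param n number of pairs.
#' @param read_len read length.
#' @param insert_mean,insert_sd fragment size model (bp).  Must satisfy
#'   `insert_mean >= 2 * read_len` (overlapping ends are disallowed).
#' @param discordant `FALSE` for concordant pairs, `TRUE` for
#'   cross-chromosome pairs.
#' @param sub_rate mean substitution rate per base.
#' @param seed RNG seed.
#' @return list with `reads1`, `reads2` and `truth` (one row per end,
#'   `pair_id`/`mate` identify the pair).
#' @export
simulate_pairs <- function(genome, n, read_len = 100L, insert_mean = 500,
                           insert_sd = 50, discordant = FALSE,
                           sub_rate = 0.01, seed) {
  set.seed(seed + 3L)
  clen <- nchar(genome)
  cls <- if (discordant) "pair_discordant" else "pair_concordant"
  if (!discordant) {
    if (insert_mean < 2 * read_len)
      stop("insert size smaller than twice the read length: ends would overlap")
    okc <- names(genome)[clen >= insert_mean + 8 * insert_sd]
    if (length(okc) == 0)
      stop("no chromosome long enough for the requested insert size")
  } else if (length(genome) < 2) {
    stop("discordant mode needs at least 2 chromosomes")
  }
  mk <- function(id, chrom, pos, strand) {
    slice <- substr(genome[[chrom]], pos + 1, pos + read_len)
    oriented <- if (strand == "-") revcomp(slice) else slice
    synth_errors(oriented, sub_rate)
  }
  ids <- sprintf("%s_%06d", if (discordant) "pd" else "pc", seq_len(n))
  t1 <- t2 <- empty_truth()
  s1 <- q1 <- s2 <- q2 <- character(n)
  for (i in seq_len(n)) {
    if (!discordant) {
      frag <- max(2 * read_len, round(rnorm(1, insert_mean, insert_sd)))
      cc <- sample(okc, 1, prob = clen[okc] - frag + 1)
      f0 <- sample.int(clen[cc] - frag + 1L, 1L) - 1L
      # R1 is the forward end of the fragment, R2 the reverse end
      p1 <- f0; st1 <- "+"
      p2 <- f0 + frag - read_len; st2 <- "-"
    } else {
      cc1 <- names(genome)[1]; cc2 <- names(genome)[2]
      p1 <- sample.int(clen[cc1] - read_len + 1L, 1L) - 1L
      p2 <- sample.int(clen[cc2] - read_len + 1L, 1L) - 1L
      st1 <- sample(c("+", "-"), 1); st2 <- sample(c("+", "-"), 1)
      cc <- cc1
    }
    chrom2 <- if (discordant) names(genome)[2] else cc
    e1 <- mk(ids[i], cc, p1, st1)
    e2 <- mk(ids[i], chrom2, p2, st2)
    s1[i] <- e1$seq; q1[i] <- e1$qual
    s2[i] <- e2$seq; q2[i] <- e2$qual
    t1 <- rbind(t1, data.frame(read_id = paste0(ids[i], "/1"), class = cls,
                               chrom = cc, pos = p1, strand = st1,
                               read_len = read_len, n_mm = e1$n_mm,
                               indel_spec = ""))
    t2 <- rbind(t2, data.frame(read_id = paste0(ids[i], "/2"), class = cls,
                               chrom = chrom2, pos = p2, strand = st2,
                               read_len = read_len, n_mm = e2$n_mm,
                               indel_spec = ""))
  }
  t1$pair_id <- ids; t1$mate <- 1L
  t2$pair_id <- ids; t2$mate <- 2L
  list(reads1 = read_set(paste0(ids, "/1"), s1, q1),
       reads2 = read_set(paste0(ids, "/2"), s2, q2),
       truth = rbind(t1, t2))
}

# ---- structural-variant rearrangement ---------------------------------------

#' Apply structural-variant events to a genome
#'
#' Deterministically reconstructs the rearranged genome from a reference and
#' an event table (the inverse bookkeeping of [rearrange_genome()]): the same
#' events always yield the same rearranged sequence, so recorded events can
#' be replayed to verify a rearrangement.
#'
#' @param genome the reference [genome()].
#' @param events event table as produced by [rearrange_genome()].
#' @return list with the rearranged `genome` and a `breakpoints` table
#'   mapping junction positions (rearranged coordinates, 0-based position of
#'   the first base after the junction) to their events.
#' @export
apply_sv_events <- function(genome, events) {
  piece <- function(chrom, s, e) substr(genome[[chrom]], s + 1, e)
  out <- list(); bp <- list()
  for (cn in names(genome)) {
    ev <- events[events$chrom == cn & events$type %in%
                   c("deletion", "inversion", "duplication"), , drop = FALSE]
    acc <- events[events$acceptor_chrom %in% cn &
                    events$type %in% c("insertion", "translocation"), ,
                  drop = FALSE]
    cut <- events[events$src_chrom %in% cn & events$type == "translocation", ,
                  drop = FALSE]
    edits <- rbind(
      if (nrow(ev)) data.frame(at = ev$start, end = ev$end, kind = ev$type,
                               id = ev$event_id, src_chrom = ev$chrom,
                               src_start = ev$start, src_end = ev$end),
      if (nrow(acc)) data.frame(at = acc$acceptor_pos, end = acc$acceptor_pos,
                                kind = "insert_piece", id = acc$event_id,
                                src_chrom = acc$src_chrom,
                                src_start = acc$src_start,
                                src_end = acc$src_end),
      if (nrow(cut)) data.frame(at = cut$src_start, end = cut$src_end,
                                kind = "cut_piece", id = cut$event_id,
                                src_chrom = cut$src_chrom,
                                src_start = cut$src_start,
                                src_end = cut$src_end))
    parts <- character(0)
    outpos <- 0
    bps <- data.frame(pos = numeric(0), event_id = integer(0),
                      type = character(0))
    cur <- 0
    if (!is.null(edits) && nrow(edits)) {
      edits <- edits[order(edits$at), , drop = FALSE]
      for (r in seq_len(nrow(edits))) {
        pre <- piece(cn, cur, edits$at[r])
        parts <- c(parts, pre); outpos <- outpos + nchar(pre)
        kind <- edits$kind[r]; id <- edits$id[r]
        if (kind == "deletion" || kind == "cut_piece") {
          bps <- rbind(bps, data.frame(pos = outpos, event_id = id,
                                       type = kind))
        } else if (kind == "inversion") {
          seg <- revcomp(piece(cn, edits$at[r], edits$end[r]))
          bps <- rbind(bps, data.frame(pos = c(outpos, outpos + nchar(seg)),
                                       event_id = id, type = kind))
          parts <- c(parts, seg); outpos <- outpos + nchar(seg)
        } else if (kind == "duplication") {
          seg <- piece(cn, edits$at[r], edits$end[r])
          bps <- rbind(bps, data.frame(pos = outpos + nchar(seg),
                                       event_id = id, type = kind))
          parts <- c(parts, seg, seg); outpos <- outpos + 2 * nchar(seg)
        } else if (kind == "insert_piece") {
          seg <- piece(edits$src_chrom[r], edits$src_start[r], edits$src_end[r])
          bps <- rbind(bps, data.frame(pos = c(outpos, outpos + nchar(seg)),
                                       event_id = id, type = "insertion_site"))
          parts <- c(parts, seg); outpos <- outpos + nchar(seg)
        }
        cur <- edits$end[r]
      }
    }
    parts <- c(parts, piece(cn, cur, nchar(genome[[cn]])))
    out[[cn]] <- paste(parts, collapse = "")
    if (nrow(bps)) bps$chrom <- cn
    bp[[cn]] <- bps
  }
  bp <- do.call(rbind, bp[vapply(bp, nrow, integer(1)) > 0])
  if (is.null(bp)) bp <- data.frame(pos = numeric(0), event_id = integer(0),
                                    type = character(0), chrom = character(0))
  rownames(bp) <- NULL
  list(genome = genome(unlist(out)), breakpoints = bp)
}

#' Rearrange a genome with structural variants
#'
#' Samples non-overlapping deletion, insertion, duplication, inversion and
#' translocation events and applies them via [apply_sv_events()].
#' Insertions and translocations are donor-derived: the inserted sequence is
#' copied (or cut) from another locus of the same genome, the way SV
#' simulators place them, so breakpoint-spanning read tails remain mappable
#' against the reference.
#'
#' @param genome the reference [genome()].
#' @param n_events number of events to place.
#' @param type_mix named probability vector over the five event types
#'   (default uniform).
#' @param size_range event length range in bp (default 100-2000).
#' @param seed RNG seed.
#' @return list with the rearranged `genome`, the `events` table and the
#'   `breakpoints` table (rearranged coordinates).
#' @export
rearrange_genome <- function(genome, n_events = 20L,
                             type_mix = c(deletion = 0.2, insertion = 0.2,
                                          duplication = 0.2, inversion = 0.2,
                                          translocation = 0.2),
                             size_range = c(100L, 2000L), seed) {
  set.seed(seed + 4L)
  used <- lapply(genome, function(x) data.frame(s = numeric(0), e = numeric(0)))
  margin <- 200
  reserve <- function(chrom, len) {
    n <- nchar(genome[[chrom]])
    if (n < len + 2 * margin) return(NULL)
    for (try in 1:50) {
      s <- sample.int(n - len - margin, 1) + margin %/% 2
      iv <- used[[chrom]]
      if (!any(pmax(iv$s, s - margin) < pmin(iv$e, s + len + margin))) {
        used[[chrom]] <<- rbind(iv, data.frame(s = s, e = s + len))
        return(s)
      }
    }
    NULL
  }
  events <- data.frame(event_id = integer(0), type = character(0),
                       chrom = character(0), start = numeric(0),
                       end = numeric(0), acceptor_chrom = character(0),
                       acceptor_pos = numeric(0), src_chrom = character(0),
                       src_start = numeric(0), src_end = numeric(0))
  id <- 0L
  tries <- 0L
  while (id < n_events && tries < 20L * n_events) {
    tries <- tries + 1L
    type <- sample(names(type_mix), 1, prob = type_mix)
    len <- sample(size_range[1]:size_range[2], 1)
    host <- sample(names(genome), 1)
    if (type %in% c("deletion", "inversion", "duplication")) {
      s <- reserve(host, len)
      if (is.null(s)) next
      id <- id + 1L
      events <- rbind(events, data.frame(
        event_id = id, type = type, chrom = host, start = s, end = s + len,
        acceptor_chrom = NA, acceptor_pos = NA, src_chrom = NA,
        src_start = NA, src_end = NA))
    } else {
      donor <- sample(names(genome), 1)
      ds <- reserve(donor, len)
      if (is.null(ds)) next
      ap <- reserve(host, 1)
      if (is.null(ap)) next
      id <- id + 1L
      events <- rbind(events, data.frame(
        event_id = id, type = type, chrom = NA, start = NA, end = NA,
        acceptor_chrom = host, acceptor_pos = ap, src_chrom = donor,
        src_start = ds, src_end = ds + len))
    }
  }
  if (id == 0) stop("could not place any SV event")
  res <- apply_sv_events(genome, events)
  list(genome = res$genome, events = events, breakpoints = res$breakpoints)
}

#' Simulate reads spanning SV breakpoints
#'
#' Draws reads from the rearranged genome that straddle recorded junctions
#' with at least `min_flank` bases on each side.  Reads are error-free by
#' default, which isolates breakpoint geometry from base-call noise when
#' exercising clipped-tail realignment.
#'
#' @param rearranged rearranged [genome()] from [rearrange_genome()].
#' @param breakpoints its breakpoint table.
#' @param n number of reads.
#' @param read_len read length.
#' @param min_flank minimum bases on each side of the junction.
#' @param sub_rate substitution rate (default 0 = error-free).
#' @param seed RNG seed.
#' @return list with `reads` and `truth` (junction position and event id per
#'   read; `pos` is the 0-based leftmost origin on the rearranged genome).
#' @export
simulate_breakpoint_reads <- function(rearranged, breakpoints, n,
                                      read_len = 100L, min_flank = 25L,
                                      sub_rate = 0, seed) {
  set.seed(seed + 5L)
  stopifnot(nrow(breakpoints) > 0, min_flank * 2 <= read_len)
  ok <- breakpoints$pos >= min_flank &
    breakpoints$pos <= nchar(rearranged)[breakpoints$chrom] - min_flank
  bps <- breakpoints[ok, , drop = FALSE]
  stopifnot(nrow(bps) > 0)
  pick <- sample.int(nrow(bps), n, replace = TRUE)
  ids <- sprintf("sv_%06d", seq_len(n))
  seqs <- quals <- character(n)
  truth <- data.frame(read_id = ids, class = "sv",
                      chrom = bps$chrom[pick], pos = NA_real_,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      read_len = read_len, n_mm = 0L, indel_spec = "",
                      bp_pos = bps$pos[pick], event_id = bps$event_id[pick],
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cl <- nchar(rearranged[[truth$chrom[i]]])
    off <- sample(min_flank:(read_len - min_flank), 1)
    p0 <- min(max(0, truth$bp_pos[i] - off), cl - read_len)
    truth$pos[i] <- p0
    slice <- substr(rearranged[[truth$chrom[i]]], p0 + 1, p0 + read_len)
    oriented <- if (truth$strand[i] == "-") revcomp(slice) else slice
    se <- synth_errors(oriented, sub_rate)
    seqs[i] <- se$seq; quals[i] <- se$qual
    truth$n_mm[i] <- se$n_mm
  }
  list(reads = read_set(ids, seqs, quals), truth = truth)
}

#' Write a truth table (or SV event table) as TSV
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
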