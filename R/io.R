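#' Reverse-complement DNA strings
#'
#' @param x character vector of sequences over `A,C,G,T,N` (case-insensitive).
#' @return character vector of reverse complements (uppercase).
#' @export
revcomp <- function(x) {
  vapply(x, function(s)
    rawToChar(rev(charToRaw(chartr("ACGTacgt", "TGCAtgca", s)))),
    character(1), USE.NAMES = FALSE)
}

#' Construct a genome object
#'
#' A genome is a named character vector of uppercase chromosome sequences over
#' `{A,C,G,T,N}`.  Names must be unique and non-empty.
#'
#' @param sequences named character vector of sequences.
#' @return object of class `"genome"` with attribute `total_length`.
#' @export
genome <- function(sequences) {
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm))) stop("genome sequences must be named")
  if (anyDuplicated(nm)) stop("duplicate sequence name in genome")
  seqs <- gsub("[^ACGTN]", "N", toupper(as.character(sequences)))
  names(seqs) <- nm
  structure(seqs, total_length = sum(nchar(seqs)), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome: %d sequence(s), %d bp total\n",
              length(x), attr(x, "total_length")))
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' Lowercase input is uppercased and IUPAC ambiguity codes (or any character
#' outside `A,C,G,T,N`) are mapped to `N`.
#'
#' @param path FASTA file.
#' @return a [genome()] object.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readDNAStringSet(path),
                 error = function(e) stop("FASTA format error: ",
                                          conditionMessage(e), call. = FALSE))
  if (length(ss) == 0) stop("FASTA format error: no sequences in ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) stop("FASTA format error: duplicate sequence name")
  genome(setNames(as.character(ss), nm))
}

#' Read FASTQ (Phred+33) into a read set
#'
#' @param path FASTQ file with 4-line records.
#' @return data.frame of class `"read_set"` with columns `id`, `seq`
#'   (uppercase bases) and `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  parsed <- tryCatch({
    ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
    q <- as.character(S4Vectors::mcols(ss)$qualities)
    s <- toupper(as.character(ss))
    if (any(nchar(q, type = "bytes") != nchar(s, type = "bytes")))
      stop("quality length differs from sequence length")
    qi <- unlist(lapply(q, function(z) utf8ToInt(z) - 33L))
    rng <- range(qi, 0L)
    if (rng[1] < 0 || rng[2] > 93) stop("Phred score outside [0, 93]")
    list(id = sub("\\s.*$", "", names(ss)), q = q, s = s)
  }, error = function(e) stop("FASTQ format error: ", conditionMessage(e),
                              call. = FALSE))
  read_set(parsed$id, parsed$s, parsed$q)
}

#' Construct a read set
#'
#' @param id,seq,qual parallel character vectors; `qual` is Phred+33 encoded
#'   and must match `seq` in length record by record.
#' @return data.frame of class `"read_set"`.
#' @export
read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual)))
    stop("sequence/quality length mismatch")
  structure(data.frame(id = as.character(id), seq = as.character(seq),
                       qual = as.character(qual), stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Decode a Phred+33 quality string to integer scores
#' @param qual quality string.
#' @return integer vector of Phred scores.
#' @export
qual_ints <- function(qual) utf8ToInt(qual) - 33L

#' Write a read set to FASTQ
#' @param reads a [read_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), 4)] <- paste0("@", reads$id)
  lines[seq(2, length(lines), 4)] <- reads$seq
  lines[seq(3, length(lines), 4)] <- "+"
  lines[seq(4, length(lines), 4)] <- reads$qual
  writeLines(lines, path)
  invisible(path)
}

# ---- CIGAR utilities ---------------------------------------------------------

#' Parse a CIGAR string
#'
#' Only the codes `M`, `I`, `D` and `S` are used by this package; `S` may only
#' appear at the ends and adjacent operations never share a code.
#'
#' @param cigar CIGAR string such as `"65M35S"`.
#' @return data.frame with columns `len` (integer) and `op` (character).
#' @export
parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDS]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDS]", cigar))[[1]]
  if (length(toks) == 0 || sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  data.frame(len = as.integer(sub("[MIDS]$", "", toks)),
             op = substring(toks, nchar(toks)), stringsAsFactors = FALSE)
}

#' Collapse parsed CIGAR operations back into a string
#' @param ops data.frame with `len` and `op`, as from [parse_cigar()]; runs of
#'   the same code are merged and zero-length operations dropped.
#' @return CIGAR string.
#' @export
cigar_string <- function(ops) {
  keep <- ops$len > 0
  len <- ops$len[keep]; op <- ops$op[keep]
  if (length(op) == 0) return("")
  j <- 1L
  for (i in seq_along(op)[-1]) {
    if (op[i] == op[j]) len[j] <- len[j] + len[i]
    else { j <- j + 1L; op[j] <- op[i]; len[j] <- len[i] }
  }
  paste0(len[seq_len(j)], op[seq_len(j)], collapse = "")
}

#' Read and reference spans of a CIGAR
#'
#' The read span counts `M + I + S`, the reference span `M + D`.
#'
#' @param cigar CIGAR string.
#' @return named integer vector `c(read = ..., ref = ...)`.
#' @export
cigar_span <- function(cigar) {
  ops <- parse_cigar(cigar)
  c(read = sum(ops$len[ops$op %in% c("M", "I", "S")]),
    ref = sum(ops$len[ops$op %in% c("M", "D")]))
}

# checks the package-wide CIGAR invariants for a read of the given length
validate_cigar <- function(cigar, read_len) {
  ops <- parse_cigar(cigar)
  if (any(ops$len <= 0)) stop("non-positive CIGAR length")
  s_idx <- which(ops$op == "S")
  if (length(s_idx) && !all(s_idx %in% c(1L, nrow(ops))))
    stop("soft clips only allowed at CIGAR ends")
  if (nrow(ops) > 1 && any(ops$op[-1] == ops$op[-nrow(ops)]))
    stop("adjacent CIGAR operations share a code")
  if (unname(cigar_span(cigar)["read"]) != read_len)
    stop("CIGAR read span does not equal read length")
  invisible(TRUE)
}

# ---- SAM output --------------------------------------------------------------

# data.frame constructor without the deparse/validation overhead of
# data.frame(); columns must be equal-length and pre-named
fast_df <- function(cols) {
  n <- if (length(cols)) length(cols[[1]]) else 0L
  structure(cols, class = "data.frame", row.names = .set_row_names(n))
}

# FLAG bits
FLAG_PAIRED <- 1L; FLAG_PROPER <- 2L; FLAG_UNMAPPED <- 4L
FLAG_MATE_UNMAPPED <- 8L; FLAG_REVERSE <- 16L; FLAG_MATE_REVERSE <- 32L
FLAG_FIRST <- 64L; FLAG_LAST <- 128L; FLAG_SUPPLEMENTARY <- 2048L

# empty alignment table with the column layout used throughout the package;
# `pos` is 0-based internally and converted to 1-based only here in write_sam
alignment_table <- function(n = 0) {
  fast_df(list(
    read_id = character(n), chrom = character(n), pos = numeric(n),
    strand = character(n), cigar = character(n), score = numeric(n),
    mapq = integer(n), mapped = logical(n),
    is_supplementary = logical(n), method = character(n),
    seq = character(n), qual = character(n),
    paired = logical(n), mate = integer(n), proper = logical(n),
    mate_chrom = character(n), mate_pos = numeric(n),
    mate_strand = character(n), mate_mapped = logical(n),
    tlen = numeric(n), rescued = logical(n)))
}

# fill missing alignment-table columns with defaults so partial producers can
# hand any subset to write_sam
complete_alignment_table <- function(df) {
  tmpl <- alignment_table(1)
  for (cn in names(tmpl)) {
    if (is.null(df[[cn]])) {
      df[[cn]] <- rep(switch(cn,
        mapped = TRUE, paired = FALSE, proper = FALSE, mate_mapped = FALSE,
        is_supplementary = FALSE, rescued = FALSE,
        mate = NA_integer_, mapq = 0L, score = NA_real_,
        tlen = 0, mate_pos = NA_real_,
        mate_chrom = NA_character_, mate_strand = NA_character_,
        method = NA_character_, NA_character_), nrow(df))
    }
  }
  df[, names(tmpl)]
}

#' Write alignments as SAM
#'
#' Emits an `@HD`/`@SQ` header and one record per row.  Internal coordinates
#' are 0-based; `POS` is converted to 1-based here, the single conversion
#' point in the package.  Reverse-strand records store the reverse complement
#' of the read with reversed qualities, per the SAM convention.
#'
#' @param alignments alignment table (see [align_reads()]); unmapped reads get
#'   FLAG 4, supplementary records FLAG 2048, proper pairs FLAGs 1+2.
#' @param genome the reference [genome()] the alignments refer to.
#' @param path output SAM file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  aln <- complete_alignment_table(alignments)
  chrlen <- nchar(genome)
  ok <- !aln$mapped | (aln$chrom %in% names(genome))
  if (!all(ok)) stop("alignment references unknown sequence")
  spans <- vapply(aln$cigar[aln$mapped], function(cg) cigar_span(cg)["ref"],
                  numeric(1))
  if (any(aln$pos[aln$mapped] + spans > chrlen[aln$chrom[aln$mapped]]))
    stop("internal error: alignment beyond sequence end")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), chrlen),
           "@PG\tID:relign\tPN:relign\tVN:0.1.0")
  flag <- integer(nrow(aln))
  flag <- flag + ifelse(aln$paired, FLAG_PAIRED, 0L)
  flag <- flag + ifelse(aln$paired & aln$proper, FLAG_PROPER, 0L)
  flag <- flag + ifelse(!aln$mapped, FLAG_UNMAPPED, 0L)
  flag <- flag + ifelse(aln$paired & !aln$mate_mapped, FLAG_MATE_UNMAPPED, 0L)
  flag <- flag + ifelse(aln$mapped & aln$strand == "-", FLAG_REVERSE, 0L)
  flag <- flag + ifelse(aln$paired & aln$mate_mapped &
                          !is.na(aln$mate_strand) & aln$mate_strand == "-",
                        FLAG_MATE_REVERSE, 0L)
  flag <- flag + ifelse(aln$paired & !is.na(aln$mate) & aln$mate == 1L,
                        FLAG_FIRST, 0L)
  flag <- flag + ifelse(aln$paired & !is.na(aln$mate) & aln$mate == 2L,
                        FLAG_LAST, 0L)
  flag <- flag + ifelse(aln$is_supplementary, FLAG_SUPPLEMENTARY, 0L)
  seq_out <- ifelse(aln$mapped & aln$strand == "-", revcomp(aln$seq), aln$seq)
  qual_out <- ifelse(aln$mapped & aln$strand == "-",
                     vapply(aln$qual, function(q)
                       intToUtf8(rev(utf8ToInt(q))), character(1)),
                     aln$qual)
  rname <- ifelse(aln$mapped, aln$chrom, "*")
  posn <- ifelse(aln$mapped, aln$pos + 1, 0)
  cg <- ifelse(aln$mapped, aln$cigar, "*")
  rnext <- ifelse(aln$paired & aln$mate_mapped & !is.na(aln$mate_chrom),
                  ifelse(aln$mate_chrom == rname & aln$mapped, "=",
                         aln$mate_chrom), "*")
  pnext <- ifelse(aln$paired & aln$mate_mapped & !is.na(aln$mate_pos),
                  aln$mate_pos + 1, 0)
  rec <- sprintf("%s\t%d\t%s\t%.0f\t%d\t%s\t%s\t%.0f\t%.0f\t%s\t%s",
                 aln$read_id, flag, rname, posn, aln$mapq, cg, rnext, pnext,
                 ifelse(is.na(aln$tlen), 0, aln$tlen), seq_out, qual_out)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
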