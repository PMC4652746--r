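#' Build a genome index for exact and approximate substring queries
#'
#' The index is a hashed k-mer position table (sorted by k-mer code) over the
#' concatenated chromosomes.  Queries are answered by pigeonhole candidate
#' generation followed by full verification, so results are exactly the set of
#' genomic positions where the pattern occurs -- no false positives or missed
#' hits.  Positions containing `N` never match.  Patterns shorter than the
#' pigeonhole part length are answered by a direct bounded scan; the query
#' contract is identical either way.
#'
#' @param genome a [genome()] object.
#' @param k k-mer width of the hash (default 10, which keeps the parts of a
#'   75-bp seed split into 7 pigeonhole pieces at or above the hash width).
#' @return an environment of class `"genome_index"`.
#' @export
build_index <- function(genome, k = 10L) {
  stopifnot(inherits(genome, "genome"))
  if (all(gsub("N", "", genome) == ""))
    stop("genome contains no indexable bases (all N)")
  idx <- new.env(parent = emptyenv())
  idx$genome <- genome
  idx$k <- as.integer(k)
  idx$chrom_names <- names(genome)
  idx$ptr <- build_index_cpp(unname(as.character(genome)), idx$k)
  class(idx) <- "genome_index"
  idx
}

# the external pointer dies across sessions (e.g. after load_index); rebuild
# transparently from the stored genome
index_ptr <- function(index) {
  stopifnot(inherits(index, "genome_index"))
  if (!ptr_valid_cpp(index$ptr))
    index$ptr <- build_index_cpp(unname(as.character(index$genome)), index$k)
  index$ptr
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index: %d sequence(s), %d bp, k = %d\n",
              length(x$genome), attr(x$genome, "total_length"), x$k))
  invisible(x)
}

#' Save / load a genome index
#'
#' The serialized file carries a format-version header; loading rebuilds the
#' in-memory query structure from the stored genome.
#'
#' @param index a `"genome_index"`.
#' @param path file path.
#' @return `path` (save) or the rebuilt index (load).
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "genome_index"))
  saveRDS(list(format = "relign-index", version = 1L,
               genome = index$genome, k = index$k), path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "relign-index"))
    stop("not a relign index file")
  if (obj$version != 1L) stop("unsupported index format version ", obj$version)
  build_index(obj$genome, obj$k)
}

#' Exact occurrences of a pattern
#'
#' Forward-strand queries return the 0-based leftmost positions of the
#' pattern; reverse-strand queries return the positions of its reverse
#' complement (still leftmost on the forward reference).
#'
#' @param index a `"genome_index"`.
#' @param pattern string over `{A,C,G,T}` (a pattern containing `N` matches
#'   nowhere).
#' @param strand `"+"` or `"-"`.
#' @return data.frame with columns `chrom` and `pos` (0-based), ordered by
#'   `(chrom, pos)`.
#' @export
find_exact <- function(index, pattern, strand = "+") {
  stopifnot(strand %in% c("+", "-"))
  pat <- if (strand == "-") revcomp(pattern) else toupper(pattern)
  df <- find_exact_cpp(index_ptr(index), pat)
  data.frame(chrom = index$chrom_names[df$chrom_idx], pos = df$pos,
             stringsAsFactors = FALSE)
}

#' All occurrences within k mismatches
#'
#' Complete k-mismatch search: every position whose Hamming distance to the
#' pattern (or its reverse complement for `strand = "-"`) is at most `k`,
#' together with the exact distance.
#'
#' @param index a `"genome_index"`.
#' @param pattern string over `{A,C,G,T}`.
#' @param k maximum mismatches, `k <= 5`; pattern must be at least `2k` long.
#' @param strand `"+"` or `"-"`.
#' @return data.frame with columns `chrom`, `pos` (0-based), `mismatches`.
#' @export
find_k_mismatch <- function(index, pattern, k, strand = "+") {
  stopifnot(strand %in% c("+", "-"), k >= 0, k <= 5,
            nchar(pattern) >= 2 * k)
  pat <- if (strand == "-") revcomp(pattern) else toupper(pattern)
  df <- find_kmm_cpp(index_ptr(index), pat, as.integer(k))
  data.frame(chrom = index$chrom_names[df$chrom_idx], pos = df$pos,
             mismatches = df$mismatches, stringsAsFactors = FALSE)
}
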