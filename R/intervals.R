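#' Build an exon chain
#'
#' An exon chain is a tibble of non-overlapping genomic intervals sharing one
#' contig and strand, sorted in ascending genomic coordinate, with columns
#' `contig`, `start`, `end`, `strand`. Coordinates are 0-based half-open
#' throughout the package; GTF/GFF3 coordinates are converted at the I/O
#' boundary.
#'
#' @param contig Contig name (single string).
#' @param starts,ends Integer vectors of 0-based half-open interval bounds.
#' @param strand `"+"` or `"-"`.
#' @return A tibble with class `txh_chain` prepended.
#' @export
#' @examples
#' exon_chain("chr1", c(100, 300), c(200, 500), "+")
exon_chain <- function(contig, starts, ends, strand) {
  if (length(contig) != 1 || !nzchar(contig)) abort("`contig` must be one non-empty string.")
  if (!strand %in% c("+", "-")) abort('`strand` must be "+" or "-".')
  if (length(starts) != length(ends)) abort("`starts` and `ends` lengths differ.")
  ch <- tibble(contig = contig, start = as.integer(starts),
               end = as.integer(ends), strand = strand)
  ch <- dplyr::arrange(ch, .data$start)
  validate_chain(ch)
  class(ch) <- c("txh_chain", class(ch))
  ch
}

validate_chain <- function(ch) {
  if (nrow(ch) == 0) return(invisible(ch))
  if (any(ch$start < 0) || any(ch$start >= ch$end))
    abort("intervals must satisfy 0 <= start < end.")
  if (length(unique(ch$contig)) > 1 || length(unique(ch$strand)) > 1)
    abort("all intervals in a chain must share contig and strand.")
  if (nrow(ch) > 1) {
    gaps <- ch$start[-1] - ch$end[-nrow(ch)]
    if (any(gaps < 1)) abort("chain intervals must be separated by >= 1 base (non-empty introns).")
  }
  invisible(ch)
}

chain_width <- function(ch) sum(ch$end - ch$start)

#' Compare two exon chains for exact structural equality
#'
#' Chains are equal iff contig, strand, and the full ordered list of
#' (start, end) pairs match exactly. This is the primitive behind
#' identifier-independent transcript matching: two transcripts have "the
#' same exon structure" exactly when their chains compare equal.
#'
#' @param a,b Interval tibbles as built by [exon_chain()].
#' @return `TRUE` or `FALSE`.
#' @export
chains_equal <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  if (nrow(a) == 0) return(TRUE)
  a$contig[1] == b$contig[1] && a$strand[1] == b$strand[1] &&
    all(a$start == b$start) && all(a$end == b$end)
}

# Intron intervals (gaps) of a chain, as a tibble in ascending order.
chain_introns <- function(ch) {
  if (nrow(ch) < 2)
    return(tibble(contig = character(), start = integer(),
                  end = integer(), strand = character()))
  tibble(contig = ch$contig[1],
         start = ch$end[-nrow(ch)],
         end = ch$start[-1],
         strand = ch$strand[1])
}

# Splice-junction key set: "end|start" per intron, order-free comparison.
junction_keys <- function(ch) {
  intr <- chain_introns(ch)
  paste0(intr$start, "|", intr$end)
}

# TRUE if position (0-based) lies in any interval of the chain.
point_in_chain <- function(ch, pos) {
  any(pos >= ch$start & pos < ch$end)
}

# TRUE if [s, e) overlaps any interval.
span_overlaps_chain <- function(ch, s, e) {
  any(pmax(ch$start, s) < pmin(ch$end, e))
}

# All 0-based positions covered by the chain (small fixtures only; used by
# oracles and coverage arithmetic).
chain_positions <- function(ch) {
  if (nrow(ch) == 0) return(integer())
  unlist(map2(ch$start, ch$end, function(s, e) seq.int(s, e - 1L)))
}

# Does chain `outer` contain chain `inner` base-by-base?
chain_contains <- function(outer, inner) {
  if (nrow(inner) == 0) return(TRUE)
  ip <- chain_positions(inner)
  op <- chain_positions(outer)
  all(ip %in% op)
}
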