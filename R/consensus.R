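# Consensus construction, alignment matrix, trusted contexts/variants and
# per-row correction.

#' Homopolymer compression
#'
#' Removes every character identical to its predecessor, e.g.
#' `hcCompress("ATTTCAA")` is `"ATCA"`.
#'
#' @param s string.
#' @return compressed string.
#' @export
hcCompress <- function(s) .cpp_hc(s)

#' Consensus of supporting segments
#'
#' Builds a partial-order alignment graph from the segments (at most
#' `maxSeqToSpoa` of them, in support order) and returns the heaviest-bundle
#' consensus path.
#'
#' @param segments character vector of segment sequences.
#' @param maxSeqToSpoa cap on the number of segments entering the graph.
#' @return consensus string.
#' @export
buildConsensus <- function(segments, maxSeqToSpoa = 200L) {
  if (!length(segments)) stop("no segments to build a consensus from")
  .cpp_poa_consensus(segments[seq_len(min(length(segments), maxSeqToSpoa))])
}

#' Multi-alignment matrix of segments against a consensus
#'
#' Each segment is aligned pairwise to the consensus with unit costs;
#' insertions relative to the consensus open columns in which the consensus
#' row (and rows without that insertion) hold `-`. Removing `-` from any row
#' reproduces its segment.
#'
#' @param segments character vector.
#' @param consensus consensus string.
#' @return list with `rows` (character vector of equal-width aligned rows)
#'   and `consensusRow`.
#' @export
buildMatrix <- function(segments, consensus) {
  stopifnot(nchar(consensus) > 0)
  res <- .cpp_build_matrix(segments, consensus)
  list(rows = as.character(res$rows),
       consensusRow = res$consensus_row)
}

#' Trusted-context occurrence threshold
#'
#' A context `b` differing from the consensus context `cPrime` is trusted
#' when it occurs at least `max(3, m * T / min(ed(c', b), ed(HC(c'),
#' HC(b))))` times among the `m` matrix rows. Gap symbols are stripped
#' before the edit distances. When the two contexts are identical under
#' homopolymer compression the variant is a homopolymer-length variation
#' and is not considered (returns `NA`).
#'
#' @param mRows number of segments in the alignment matrix.
#' @param T trust fraction (default 0.1).
#' @param cPrime consensus context (matrix symbols, may include `-`).
#' @param b candidate context (must differ from `cPrime`).
#' @return numeric threshold, or `NA` when the variant is not considered.
#' @export
trustedThreshold <- function(mRows, T, cPrime, b) {
  stopifnot(cPrime != b)
  strip <- function(x) gsub("-", "", x, fixed = TRUE)
  cs <- strip(cPrime); bs <- strip(b)
  den <- min(.cpp_edit_distance(cs, bs),
             .cpp_edit_distance(hcCompress(cs), hcCompress(bs)))
  if (den == 0L) return(NA_real_)
  max(3, mRows * T / den)
}

#' Trusted contexts and variants per matrix column
#'
#' For every column the consensus context is trusted; any other context
#' occurring in at least three rows and meeting [trustedThreshold()] is
#' trusted with its column symbol as variant. Windows span
#' `floor(k/2)` columns on each side, truncated at the matrix edges.
#'
#' @param rows aligned matrix rows (equal width).
#' @param consensusRow the consensus row.
#' @param k k-mer size defining the window width.
#' @param T trust fraction.
#' @return list with one data.frame per column (`context`, `variant`,
#'   `count`, `consensus`).
#' @export
trustedSets <- function(rows, consensusRow, k = 9L, T = 0.1) {
  .cpp_trusted_sets(rows, consensusRow, as.integer(k), T)
}

#' Correct one matrix row against trusted variants
#'
#' For every column, the trusted variant whose context is nearest (edit
#' distance on gap-stripped windows) to the row's own window replaces the
#' row's symbol; all decisions are taken against the original row. Ties
#' prefer the higher-count context, then the consensus.
#'
#' @param rows aligned matrix rows.
#' @param consensusRow the consensus row.
#' @param rowIndex 1-based index of the row to correct.
#' @param k,T as in [trustedSets()].
#' @return the corrected segment (gaps removed).
#' @export
correctRow <- function(rows, consensusRow, rowIndex = 1L, k = 9L, T = 0.1) {
  as.character(.cpp_correct_rows(rows, consensusRow, as.integer(k), T,
                                 as.integer(rowIndex)))
}
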