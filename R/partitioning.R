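# Interval support with the quality-aware similarity rule, and the exact
# weighted interval scheduling solver.

#' Exact edit distance
#'
#' Unit-cost Levenshtein distance (bit-parallel implementation).
#'
#' @param a,b strings.
#' @return integer edit distance.
#' @export
editDistance <- function(a, b) .cpp_edit_distance(a, b)

#' Unit-cost global alignment
#'
#' @param a,b strings.
#' @return character vector of the two aligned strings with `-` gaps.
#' @export
globalAlign <- function(a, b) .cpp_global_align(a, b)

#' Quality-aware sequence similarity
#'
#' Two segments are similar when their edit distance is strictly below
#' `nchar(s) * (epsS + epsSPrime)`, where the epsilons are the segments'
#' mean per-base error rates inferred from quality values.
#'
#' @param s,sPrime segment strings (`s` from the read being corrected).
#' @param epsS,epsSPrime mean per-base error rates of the two segments.
#' @return logical.
#' @export
isSimilar <- function(s, sPrime, epsS, epsSPrime) {
  stopifnot(nchar(s) > 0)
  # small guard so exact boundaries (ed == |s|(eps+eps')) stay strict under
  # floating-point addition
  .cpp_edit_distance(s, sPrime) < nchar(s) * (epsS + epsSPrime) - 1e-9
}

#' Support of a candidate interval
#'
#' For the anchor pair at positions `(p, q)` on a read, counts the
#' occurrences of the same pair in other reads whose spanned segments are
#' similar ([isSimilar()]); when a read carries several occurrences, only
#' its smallest-edit-distance occurrence is tested. The read's own segment
#' always counts, so support is at least 1. The interval weight is
#' `support * (q - p - k)`.
#'
#' @param cluster a [ReadCluster-class].
#' @param readId read identifier.
#' @param p,q 0-based anchor start positions of the pair on the read.
#' @param params a [CorrectionParams-class].
#' @return list with `support`, `weight`, and a `segments` data.frame
#'   (`read_id`, `start`, `end`: 0-based half-open spans including both
#'   anchor k-mers; the first row is the read's own segment).
#' @export
computeSupport <- function(cluster, readId, p, q,
                           params = CorrectionParams()) {
  k <- params@k
  w <- if (is.na(params@w)) adaptiveWindow(length(cluster), k) else params@w
  r <- match(readId, names(cluster))
  if (is.na(r)) stop("unknown read id: ", readId)
  res <- .cpp_compute_support(
    as.character(cluster@sequences), unname(cluster@errorProbs),
    r, as.integer(p), as.integer(q), k, w, params@xmin, params@xmax)
  seg <- res$segments
  list(support = res$support, weight = res$weight,
       segments = data.frame(read_id = names(cluster)[seg[, "read"]],
                             start = seg[, "p"],
                             end = seg[, "q"] + k,
                             stringsAsFactors = FALSE))
}

#' Exact weighted interval scheduling
#'
#' Maximum-weight subset of pairwise non-overlapping half-open intervals
#' `[begin, end)`, solved by the classical O(n log n) predecessor dynamic
#' program. Adjacent selected intervals may abut exactly (`end == begin`).
#'
#' @param intervals data.frame with columns `begin`, `end`, `weight`.
#' @return the selected rows, ordered by `begin`.
#' @examples
#' iv <- data.frame(begin = c(0, 5, 0), end = c(10, 15, 15),
#'                  weight = c(5, 5, 9))
#' solveIntervalScheduling(iv)  # the two weight-5 intervals
#' @export
solveIntervalScheduling <- function(intervals) {
  if (!nrow(intervals)) return(intervals)
  sel <- .cpp_wis(as.integer(intervals$begin), as.integer(intervals$end),
                  as.numeric(intervals$weight))
  intervals[sel, , drop = FALSE]
}
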