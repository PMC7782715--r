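# Positional minimizers, anchor pairs, polyA masking, adaptive window and
# the cross-read anchor-pair index.

#' Positional minimizers of a sequence
#'
#' For every window start `p` in `[0, L - k]` the lexicographically smallest
#' k-mer starting in `[p, p + w - k + 1)` is reported (leftmost position on
#' ties); duplicate (kmer, pos) pairs from overlapping windows are collapsed.
#' Plain byte order is used, so `A < C < G < N < T`.
#'
#' @param seq nucleotide string.
#' @param k k-mer size.
#' @param w window length (`w >= k`).
#' @return data.frame with columns `kmer` and 0-based `pos`, ordered by
#'   increasing `pos`; empty if the sequence is shorter than `k`.
#' @examples
#' minimizers("AGACCAT", k = 2, w = 3)
#' @export
minimizers <- function(seq, k, w) {
  stopifnot(k >= 1, w >= k)
  res <- .cpp_minimizers(seq, as.integer(k), as.integer(w))
  data.frame(kmer = res$kmer, pos = res$pos, stringsAsFactors = FALSE)
}

#' Paired anchors from positional minimizers
#'
#' All ordered pairs of positional minimizers separated by at least `xmin`
#' and at most `xmax` nucleotides, ordered by (pos1, pos2).
#'
#' @param minis data.frame as returned by [minimizers()].
#' @param xmin,xmax distance bounds on `pos2 - pos1`.
#' @return data.frame with columns `kmer1, pos1, kmer2, pos2`.
#' @examples
#' anchorPairs(minimizers("AGACCAT", 2, 3), xmin = 2, xmax = 3)
#' @export
anchorPairs <- function(minis, xmin, xmax) {
  n <- nrow(minis)
  out <- list()
  if (n >= 2L) {
    idx <- which(outer(minis$pos, minis$pos,
                       function(a, b) b - a >= xmin & b - a <= xmax),
                 arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(minis$pos[idx[, 1L]], minis$pos[idx[, 2L]]), ,
               drop = FALSE]
    out <- data.frame(kmer1 = minis$kmer[idx[, 1L]],
                      pos1 = minis$pos[idx[, 1L]],
                      kmer2 = minis$kmer[idx[, 2L]],
                      pos2 = minis$pos[idx[, 2L]],
                      stringsAsFactors = FALSE)
    return(out)
  }
  data.frame(kmer1 = character(), pos1 = integer(),
             kmer2 = character(), pos2 = integer(),
             stringsAsFactors = FALSE)
}

#' Mask polyA anchor pairs
#'
#' Removes anchor pairs in which both k-mers consist only of A's; such pairs
#' come from polyA tails and make the anchor index redundant and repetitive.
#'
#' @param pairs data.frame as returned by [anchorPairs()].
#' @return the filtered data.frame, original order retained.
#' @export
maskPolyA <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  allA <- function(s) vapply(s, function(x)
    nchar(gsub("A", "", x, fixed = TRUE)) == 0L, logical(1), USE.NAMES = FALSE)
  keep <- !(allA(pairs$kmer1) & allA(pairs$kmer2))
  pairs[keep, , drop = FALSE]
}

#' Adaptive minimizer window for a cluster
#'
#' `w = k + floor(|C| / 500)` where `|C|` is the cluster size, so sparser
#' anchors are used for larger clusters.
#'
#' @param clusterSize number of reads in the cluster.
#' @param k k-mer size.
#' @return integer window length.
#' @examples
#' adaptiveWindow(499, 9)  # 9
#' adaptiveWindow(1000, 9) # 11
#' @export
adaptiveWindow <- function(clusterSize, k) {
  stopifnot(clusterSize >= 1)
  as.integer(k + clusterSize %/% 500L)
}

#' Anchor-pair index of a cluster
#'
#' Maps each (kmer1, kmer2) anchor pair to all of its occurrences across the
#' cluster's reads (after polyA masking). Occurrences record the read id and
#' the two 0-based anchor start positions.
#'
#' @param cluster a [ReadCluster-class].
#' @param params a [CorrectionParams-class]; `w` defaults to the adaptive
#'   rule when `NA`.
#' @return named list: for each `"KMER1|KMER2"` key a data.frame with
#'   columns `read_id`, `p`, `q`.
#' @export
buildPairIndex <- function(cluster, params = CorrectionParams()) {
  k <- params@k
  w <- if (is.na(params@w)) adaptiveWindow(length(cluster), k) else params@w
  ids <- names(cluster)
  occ <- lapply(seq_along(ids), function(i) {
    m <- minimizers(as.character(cluster@sequences[[i]]), k, w)
    pr <- maskPolyA(anchorPairs(m, params@xmin, params@xmax))
    if (!nrow(pr)) return(NULL)
    data.frame(key = paste0(pr$kmer1, "|", pr$kmer2),
               read_id = ids[i], p = pr$pos1, q = pr$pos2,
               stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, occ)
  if (is.null(occ)) return(list())
  split(occ[c("read_id", "p", "q")], occ$key)
}
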