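#' Cluster of reads from one gene family
#'
#' A `ReadCluster` holds the reads of a single cluster (typically one gene
#' family as produced by an upstream clustering tool): their sequences, their
#' per-base error probabilities derived from FASTQ quality values, and the
#' cluster identifier.
#'
#' @slot sequences [Biostrings::DNAStringSet] of read sequences, named by
#'   read identifiers.
#' @slot errorProbs list of numeric vectors, one per read, with per-base
#'   error probabilities in `(0, 1]` (length matching each sequence).
#' @slot clusterId single character, the cluster identifier.
#'
#' @export
setClass("ReadCluster",
  representation(sequences = "DNAStringSet",
                 errorProbs = "list",
                 clusterId = "character"))

setValidity("ReadCluster", function(object) {
  msgs <- character()
  n <- length(object@sequences)
  if (length(object@errorProbs) != n)
    msgs <- c(msgs, "errorProbs must have one vector per read")
  if (length(object@clusterId) != 1L || is.na(object@clusterId))
    msgs <- c(msgs, "clusterId must be a single non-NA string")
  ids <- names(object@sequences)
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "reads must have unique identifiers")
  w <- Biostrings::width(object@sequences)
  ql <- lengths(object@errorProbs)
  if (length(ql) == n && any(w != ql))
    msgs <- c(msgs, "error probability vectors must match sequence lengths")
  bad <- vapply(object@errorProbs,
                function(p) any(p <= 0 | p > 1 | is.na(p)), logical(1))
  if (any(bad))
    msgs <- c(msgs, "error probabilities must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ReadCluster
#'
#' @param sequences a [Biostrings::DNAStringSet] (or character vector) of
#'   read sequences, named by read identifiers.
#' @param errorProbs list of per-base error probability vectors, one per
#'   read, each value in `(0, 1]`. A single number recycles to a uniform
#'   per-base rate.
#' @param clusterId cluster identifier.
#' @return A [ReadCluster-class] object.
#' @examples
#' rc <- ReadCluster(c(r1 = "ACGTACGT", r2 = "ACGAACGT"), 0.07, "demo")
#' rc
#' @export
ReadCluster <- function(sequences, errorProbs = 0.07, clusterId = "cluster") {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (is.numeric(errorProbs) && length(errorProbs) == 1L)
    errorProbs <- lapply(Biostrings::width(sequences),
                         function(w) rep(errorProbs, w))
  names(errorProbs) <- names(sequences)
  new("ReadCluster", sequences = sequences,
      errorProbs = errorProbs, clusterId = as.character(clusterId))
}

#' @describeIn ReadCluster number of reads
#' @param x a `ReadCluster`
#' @export
setMethod("length", "ReadCluster", function(x) length(x@sequences))

#' @describeIn ReadCluster read identifiers
#' @export
setMethod("names", "ReadCluster", function(x) names(x@sequences))

setMethod("show", "ReadCluster", function(object) {
  cat("ReadCluster '", object@clusterId, "' with ",
      length(object@sequences), " reads\n", sep = "")
  w <- Biostrings::width(object@sequences)
  if (length(w))
    cat("  read length: ", min(w), "-", max(w), " nt; mean error prob ",
        signif(mean(unlist(object@errorProbs)), 3), "\n", sep = "")
})

#' @rdname ReadCluster
#' @param i index or read ids
#' @export
setMethod("[", "ReadCluster", function(x, i) {
  new("ReadCluster", sequences = x@sequences[i],
      errorProbs = x@errorProbs[i], clusterId = x@clusterId)
})

#' Cluster identifier
#' @param x a [ReadCluster-class]
#' @return single character
#' @export
clusterId <- function(x) x@clusterId

#' Per-base error probabilities
#' @param x a [ReadCluster-class]
#' @return list of numeric vectors, one per read
#' @export
errorProbs <- function(x) x@errorProbs

#' Read sequences of a cluster
#' @param x a [ReadCluster-class]
#' @return a [Biostrings::DNAStringSet]
#' @export
readSequences <- function(x) x@sequences


#' Correction parameters
#'
#' Tunable parameters of the correction algorithm. Defaults follow the
#' method's standard settings: k-mer size `k = 9`, minimum anchor distance
#' `xmin = 2k`, maximum anchor distance `xmax = 80`, trust fraction
#' `tFrac = 0.1`, exact mode for clusters smaller than
#' `exactInstanceLimit = 50` reads, at most `maxSeqToSpoa = 200` segments
#' entering the consensus, and batches of `maxSeq = 1000` reads. When `w` is
#' `NA` the minimizer window is set per cluster as `k + floor(|C| / 500)`.
#'
#' @slot k integer k-mer (anchor) size.
#' @slot w integer minimizer window length, or NA for the adaptive rule.
#' @slot xmin,xmax integer anchor distance bounds.
#' @slot tFrac numeric trusted-variant fraction threshold in (0, 1).
#' @slot exactInstanceLimit integer; clusters with fewer reads use exact mode.
#' @slot maxSeqToSpoa integer cap on segments used to build the consensus.
#' @slot maxSeq integer batch size within a cluster.
#' @slot mode one of "auto", "exact", "approximate".
#' @slot defaultErrorRate numeric per-base error probability assumed for
#'   reads without quality values (FASTA input).
#' @export
setClass("CorrectionParams",
  representation(k = "integer", w = "integer", xmin = "integer",
                 xmax = "integer", tFrac = "numeric",
                 exactInstanceLimit = "integer", maxSeqToSpoa = "integer",
                 maxSeq = "integer", mode = "character",
                 defaultErrorRate = "numeric"))

setValidity("CorrectionParams", function(object) {
  msgs <- character()
  k <- object@k
  if (k < 1L || k > 10L)
    msgs <- c(msgs, "k must be in 1..10")
  if (!is.na(object@w) && object@w < k)
    msgs <- c(msgs, "w must be >= k")
  if (object@xmin < k)
    msgs <- c(msgs, "xmin must be >= k")
  if (object@xmax < object@xmin)
    msgs <- c(msgs, "xmax must be >= xmin")
  if (object@tFrac <= 0 || object@tFrac >= 1)
    msgs <- c(msgs, "tFrac must be in (0, 1)")
  if (!object@mode %in% c("auto", "exact", "approximate"))
    msgs <- c(msgs, "mode must be auto, exact or approximate")
  if (object@defaultErrorRate <= 0 || object@defaultErrorRate > 1)
    msgs <- c(msgs, "defaultErrorRate must be in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CorrectionParams-class
#' @param k,w,xmin,xmax,tFrac,exactInstanceLimit,maxSeqToSpoa,maxSeq,mode,defaultErrorRate
#'   see the class slots.
#' @return a `CorrectionParams` object
#' @examples
#' CorrectionParams()
#' CorrectionParams(k = 8L, xmax = 100L)
#' @export
CorrectionParams <- function(k = 9L, w = NA_integer_, xmin = 2L * k,
                             xmax = 80L, tFrac = 0.1,
                             exactInstanceLimit = 50L, maxSeqToSpoa = 200L,
                             maxSeq = 1000L, mode = "auto",
                             defaultErrorRate = 0.07) {
  new("CorrectionParams", k = as.integer(k), w = as.integer(w),
      xmin = as.integer(xmin), xmax = as.integer(xmax), tFrac = tFrac,
      exactInstanceLimit = as.integer(exactInstanceLimit),
      maxSeqToSpoa = as.integer(maxSeqToSpoa), maxSeq = as.integer(maxSeq),
      mode = mode, defaultErrorRate = defaultErrorRate)
}

setMethod("show", "CorrectionParams", function(object) {
  cat("CorrectionParams: k=", object@k,
      " w=", ifelse(is.na(object@w), "adaptive", object@w),
      " xmin=", object@xmin, " xmax=", object@xmax,
      " T=", object@tFrac,
      " exactInstanceLimit=", object@exactInstanceLimit,
      " maxSeqToSpoa=", object@maxSeqToSpoa,
      " maxSeq=", object@maxSeq, " mode=", object@mode, "\n", sep = "")
})
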