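# Per-read and per-cluster correction orchestration, batching and the
# command-line style front end.

.resolve_w <- function(params, n) {
  if (is.na(params@w)) adaptiveWindow(n, params@k) else params@w
}

.resolve_mode <- function(params, n) {
  if (params@mode != "auto") return(params@mode)
  if (n < params@exactInstanceLimit) "exact" else "approximate"
}

#' Correct a single read within its cluster
#'
#' Builds the read's candidate intervals, solves the scheduling instance and
#' corrects each selected interval against its supporting segments.
#' Positions outside selected intervals, and the anchor k-mers themselves,
#' are returned unchanged. A read without any anchor pair is returned
#' unchanged.
#'
#' @param cluster a [ReadCluster-class] containing the read.
#' @param readId identifier of the read to correct.
#' @param params a [CorrectionParams-class].
#' @param mode `"exact"` or `"approximate"`; default follows `params`.
#' @return list with `sequence` (corrected read) and `intervals`
#'   (data.frame `begin`, `end`, `support` of the selected intervals,
#'   0-based half-open, anchors excluded).
#' @export
correctRead <- function(cluster, readId, params = CorrectionParams(),
                        mode = NULL) {
  r <- match(readId, names(cluster))
  if (is.na(r)) stop("unknown read id: ", readId)
  n <- length(cluster)
  if (is.null(mode)) mode <- .resolve_mode(params, n)
  res <- .cpp_correct_cluster(
    as.character(cluster@sequences), unname(cluster@errorProbs),
    params@k, .resolve_w(params, n), params@xmin, params@xmax,
    params@tFrac, params@maxSeqToSpoa, mode == "approximate",
    TRUE, r)
  iv <- res$intervals[[r]]
  colnames(iv) <- c("begin", "end", "support")
  list(sequence = as.character(res$corrected[r]),
       intervals = as.data.frame(iv))
}

#' Correct a whole cluster
#'
#' Chooses exact mode for clusters smaller than `exactInstanceLimit` reads
#' and the approximate (cached-segment) mode otherwise, sets the minimizer
#' window adaptively when `w` is `NA`, and processes reads in batches of at
#' most `maxSeq`. Output order matches input order and identifiers are
#' preserved; corrected bases carry a placeholder quality of Phred 30.
#'
#' @param cluster a [ReadCluster-class].
#' @param params a [CorrectionParams-class].
#' @param details when TRUE, attach the selected intervals of every read as
#'   metadata (`intervals`).
#' @return the corrected [ReadCluster-class]; `metadata`-like attributes
#'   `mode`, `w` and `batches` are stored in `attr(x, "run")`.
#' @export
correctCluster <- function(cluster, params = CorrectionParams(),
                           details = FALSE) {
  n <- length(cluster)
  if (n == 0L) return(cluster)
  mode <- .resolve_mode(params, n)
  w <- .resolve_w(params, n)
  batches <- split(seq_len(n), (seq_len(n) - 1L) %/% params@maxSeq)
  corrected <- character(n)
  intervals <- vector("list", n)
  n_no_anchor <- 0L
  for (b in batches) {
    res <- .cpp_correct_cluster(
      as.character(cluster@sequences[b]), unname(cluster@errorProbs[b]),
      params@k, w, params@xmin, params@xmax, params@tFrac,
      params@maxSeqToSpoa, mode == "approximate", details, 0L)
    corrected[b] <- as.character(res$corrected)
    n_no_anchor <- n_no_anchor + res$n_no_anchors
    if (details) intervals[b] <- res$intervals
  }
  seqs <- Biostrings::DNAStringSet(corrected)
  names(seqs) <- names(cluster)
  out <- ReadCluster(seqs, 10^(-30 / 10), clusterId(cluster))
  run <- list(mode = mode, w = w, n_batches = length(batches),
              n_reads = n, n_no_anchors = n_no_anchor)
  if (details) {
    names(intervals) <- names(cluster)
    run$intervals <- lapply(intervals, function(m) {
      colnames(m) <- c("begin", "end", "support")
      as.data.frame(m)
    })
  }
  attr(out, "run") <- run
  out
}

#' Correct FASTQ files from disk
#'
#' Front end over [correctCluster()]: a single FASTQ is treated as one
#' cluster and written to `outfolder/corrected.fastq`; a directory yields
#' one cluster per `*.fastq` file, each written under `outfolder` with its
#' cluster id. A plain-text run log (parameters, per-cluster mode and read
#' counts) is written to `outfolder/run.log`.
#'
#' @param fastq single FASTQ file (mutually exclusive with `indir`).
#' @param indir directory of per-cluster FASTQ files.
#' @param outfolder output directory (created if missing).
#' @param params a [CorrectionParams-class].
#' @return invisibly, the paths of the corrected FASTQ files.
#' @export
correctFastqFiles <- function(fastq = NULL, indir = NULL, outfolder,
                              params = CorrectionParams()) {
  if (is.null(fastq) == is.null(indir))
    stop("provide exactly one of 'fastq' or 'indir'")
  files <- findClusterFiles(if (is.null(fastq)) indir else fastq)
  dir.create(outfolder, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("k=%d xmin=%d xmax=%d T=%g exact_instance_limit=%d",
                   params@k, params@xmin, params@xmax, params@tFrac,
                   params@exactInstanceLimit),
           sprintf("w=%s max_seq_to_spoa=%d max_seq=%d mode=%s",
                   ifelse(is.na(params@w), "adaptive",
                          as.character(params@w)),
                   params@maxSeqToSpoa, params@maxSeq, params@mode))
  outs <- character(0)
  for (cid in names(files)) {
    cl <- readFastqCluster(files[[cid]], cid)
    cc <- correctCluster(cl, params)
    run <- attr(cc, "run")
    out <- if (!is.null(fastq)) file.path(outfolder, "corrected.fastq")
           else file.path(outfolder, paste0(cid, ".fastq"))
    writeFastqReads(readSequences(cc), out)
    outs <- c(outs, out)
    log <- c(log, sprintf(
      "cluster=%s reads=%d mode=%s w=%d batches=%d no_anchors=%d out=%s",
      cid, run$n_reads, run$mode, run$w, run$n_batches, run$n_no_anchors,
      out))
  }
  writeLines(log, file.path(outfolder, "run.log"))
  invisible(outs)
}
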