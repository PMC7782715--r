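# Evaluation against known truth: per-read error rates before/after
# correction, miscorrection and overcorrection.

.as_named_seqs <- function(x) {
  if (is(x, "ReadCluster")) x <- x@sequences
  if (!is.character(x)) x <- setNames(as.character(x), names(x))
  x
}

#' Evaluate corrected reads against known transcripts
#'
#' The error rate of a read is the number of alignment mismatches
#' (substitutions + insertions + deletions of a unit-cost global alignment
#' to the true transcript) divided by the alignment length. A read is
#' miscorrected when it has more mismatches after correction than before,
#' and overcorrected when its corrected sequence has a strictly smaller edit
#' distance to some other transcript than to its true transcript; the
#' overcorrection distance is `ed(true) - min(ed)` (at least 1 whenever the
#' flag is set, 0 otherwise).
#'
#' @param corrected,original named sequences ([ReadCluster-class],
#'   [Biostrings::DNAStringSet] or named character), identifiers matching
#'   `truth$read_id`.
#' @param truth data.frame with `read_id`, `transcript_id` and optionally
#'   `depth` (as from [simulateReads()]).
#' @param transcripts named sequences of the true transcripts.
#' @return list with `perRead` (data.frame: `read_id`, `depth`,
#'   `err_before`, `err_after`, `miscorrected`, `overcorrected`,
#'   `overcorrection_distance`) and `summary` (data.frame by depth:
#'   `depth`, `n`, `median_before`, `median_after`, `frac_miscorrected`,
#'   `frac_overcorrected`).
#' @export
evaluateCorrection <- function(corrected, original, truth, transcripts) {
  corrected <- .as_named_seqs(corrected)
  original <- .as_named_seqs(original)
  tx <- .as_named_seqs(transcripts)
  ids <- truth$read_id
  if (!setequal(ids, names(corrected)) || !setequal(ids, names(original)))
    stop("read identifiers of corrected/original reads and truth differ")
  n <- length(ids)
  err_b <- err_a <- dist_over <- numeric(n)
  mis <- over <- logical(n)
  mm_b <- mm_a <- integer(n)
  for (i in seq_len(n)) {
    ts <- tx[[truth$transcript_id[i]]]
    sb <- .cpp_align_stats(original[[ids[i]]], ts)
    sa <- .cpp_align_stats(corrected[[ids[i]]], ts)
    mm_b[i] <- sb[["subs"]] + sb[["ins"]] + sb[["del"]]
    mm_a[i] <- sa[["subs"]] + sa[["ins"]] + sa[["del"]]
    err_b[i] <- mm_b[i] / sb[["aln_len"]]
    err_a[i] <- mm_a[i] / sa[["aln_len"]]
    mis[i] <- mm_a[i] > mm_b[i]
    eds <- .cpp_edit_distance_many(corrected[[ids[i]]], unname(tx))
    ed_true <- eds[match(truth$transcript_id[i], names(tx))]
    over[i] <- any(eds < ed_true)
    dist_over[i] <- ed_true - min(eds)
  }
  depth <- if ("depth" %in% names(truth)) truth$depth
           else as.vector(table(truth$transcript_id)[truth$transcript_id])
  perRead <- data.frame(read_id = ids, depth = depth,
                        err_before = err_b, err_after = err_a,
                        miscorrected = mis, overcorrected = over,
                        overcorrection_distance = dist_over,
                        stringsAsFactors = FALSE)
  spl <- split(seq_len(n), depth)
  summary <- data.frame(
    depth = as.numeric(names(spl)),
    n = lengths(spl),
    median_before = vapply(spl, function(ii) median(err_b[ii]), numeric(1)),
    median_after = vapply(spl, function(ii) median(err_a[ii]), numeric(1)),
    frac_miscorrected = vapply(spl, function(ii) mean(mis[ii]), numeric(1)),
    frac_overcorrected = vapply(spl, function(ii) mean(over[ii]), numeric(1)),
    row.names = NULL)
  list(perRead = perRead, summary = summary)
}

#' Write evaluation results to disk
#'
#' Writes the per-read metrics and the by-depth summary of
#' [evaluateCorrection()] as tab-separated files (`metrics.tsv`,
#' `summary.tsv`).
#'
#' @param ev result of [evaluateCorrection()].
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
writeEvaluation <- function(ev, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- file.path(dir, "metrics.tsv")
  summary <- file.path(dir, "summary.tsv")
  utils::write.table(ev$perRead, metrics, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ev$summary, summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(metrics = metrics, summary = summary))
}
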