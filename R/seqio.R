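# FASTQ/FASTA input and output, quality/probability conversion, cluster
# discovery. Reads are stored in ReadCluster objects; per-base error
# probabilities are 10^(-Q/10) for Phred score Q (so Q = 0 means 1.0).

.phred_to_prob <- function(qual_string) {
  q <- utf8ToInt(qual_string) - 33L
  10^(-q / 10)
}

.prob_to_phred_char <- function(p) {
  q <- as.integer(round(-10 * log10(p)))
  q <- pmin(pmax(q, 0L), 93L)
  intToUtf8(q + 33L, multiple = FALSE)
}

#' Read a FASTQ file as one cluster
#'
#' Parses a 4-line-record FASTQ file (Phred+33) into a [ReadCluster-class].
#' Per-base error probabilities are derived from the quality string as
#' `10^(-Q/10)`.
#'
#' @param path FASTQ file path.
#' @param clusterId cluster identifier; defaults to the file name without
#'   extension.
#' @return a [ReadCluster-class] with reads in file order.
#' @export
readFastqCluster <- function(path, clusterId = NULL) {
  if (is.null(clusterId))
    clusterId <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': number of lines not a multiple of 4")
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(ReadCluster(Biostrings::DNAStringSet(), list(), clusterId))
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  qu <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in '", path, "'")
  bad <- which(nchar(sq) != nchar(qu))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " (", sub("^@", "", hd[bad[1L]]),
         "): sequence and quality lengths differ")
  ids <- sub("\\s.*$", "", sub("^@", "", hd))
  seqs <- Biostrings::DNAStringSet(sq)
  names(seqs) <- ids
  probs <- lapply(qu, .phred_to_prob)
  ReadCluster(seqs, probs, clusterId)
}

#' Read a FASTA file as one cluster
#'
#' Reads without quality values are assigned a uniform per-base error
#' probability (`defaultErrorRate`).
#'
#' @param path FASTA file path.
#' @param clusterId cluster identifier; defaults to the file name.
#' @param defaultErrorRate assumed per-base error probability.
#' @return a [ReadCluster-class].
#' @export
readFastaCluster <- function(path, clusterId = NULL,
                             defaultErrorRate = 0.07) {
  if (is.null(clusterId))
    clusterId <- tools::file_path_sans_ext(basename(path))
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ReadCluster(seqs, defaultErrorRate, clusterId)
}

#' Write reads to FASTQ
#'
#' Writes sequences with qualities recovered from their per-base error
#' probabilities; corrected reads carry a constant placeholder quality
#' (Phred 30) because the algorithm does not model post-correction
#' qualities.
#'
#' @param x a [ReadCluster-class], or a named character vector /
#'   [Biostrings::DNAStringSet] of sequences.
#' @param path output file path.
#' @param quality single Phred score used when `x` carries no
#'   probabilities (default 30).
#' @return invisibly, the path.
#' @export
writeFastqReads <- function(x, path, quality = 30L) {
  if (is(x, "ReadCluster")) {
    seqs <- x@sequences
    quals <- vapply(x@errorProbs, .prob_to_phred_char, character(1))
  } else {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    seqs <- x
    qc <- intToUtf8(quality + 33L)
    quals <- vapply(Biostrings::width(seqs),
                    function(w) strrep(qc, w), character(1))
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read_", seq_along(seqs))
  out <- character(4L * length(seqs))
  if (length(seqs)) {
    out[seq(1L, by = 4L, length.out = length(seqs))] <- paste0("@", ids)
    out[seq(2L, by = 4L, length.out = length(seqs))] <- as.character(seqs)
    out[seq(3L, by = 4L, length.out = length(seqs))] <- "+"
    out[seq(4L, by = 4L, length.out = length(seqs))] <- quals
  }
  writeLines(out, path)
  invisible(path)
}

#' Mean error rate over a read window
#'
#' Arithmetic mean of the per-base error probabilities over the half-open
#' window `[start, end)` (0-based), as used by the interval similarity test.
#'
#' @param read a [ReadCluster-class] with the read, or a numeric vector of
#'   probabilities.
#' @param start,end 0-based half-open window bounds.
#' @param readId read identifier when `read` is a cluster.
#' @return mean probability.
#' @export
meanErrorRate <- function(read, start, end, readId = NULL) {
  probs <- if (is(read, "ReadCluster")) {
    stopifnot(!is.null(readId))
    read@errorProbs[[readId]]
  } else read
  if (!(start >= 0 && start < end && end <= length(probs)))
    stop("invalid window [", start, ", ", end, ")")
  mean(probs[(start + 1L):end])
}

#' Discover cluster FASTQ files
#'
#' A directory yields one cluster per `*.fastq` file (the file name is the
#' cluster id); a single file is one cluster.
#'
#' @param path directory or FASTQ file.
#' @return named character vector of file paths (names = cluster ids).
#' @export
findClusterFiles <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.fastq$", full.names = TRUE))
  } else {
    if (!file.exists(path)) stop("input path not found: ", path)
    files <- path
  }
  setNames(files, tools::file_path_sans_ext(basename(files)))
}
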