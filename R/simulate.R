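# Synthetic transcripts and reads: exon-sharing isoforms of a gene, and an
# i.i.d. per-base error process with a controlled substitution/insertion/
# deletion mix. All randomness flows from explicit seeds; helpers derive
# per-replicate sub-seeds with a counter-based splitting scheme.

.split_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(counter) * 7919) %%
               2147483629) + 1L
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Synthetic gene with exon-sharing isoforms
#'
#' Draws `nExons` exon sequences uniformly over ACGT and builds `nIsoforms`
#' transcripts as distinct ordered subsets of the exons. The first isoform
#' uses all exons, so every isoform shares at least one exon with it.
#'
#' @param nIsoforms number of isoforms (`<= 2^nExons - 1`).
#' @param nExons number of exons.
#' @param exonLenRange integer range (min, max) of exon lengths.
#' @param seed integer seed; the same seed reproduces the gene exactly.
#' @param geneId gene identifier used in transcript names.
#' @param structure `"window"` draws additional isoforms as contiguous exon
#'   windows of at least two exons (alternative transcription start/end
#'   sites, the dominant isoform diversity in cDNA data); `"subset"` draws
#'   arbitrary exon subsets (alternative splicing).
#' @return a [Biostrings::DNAStringSet] of transcripts named
#'   `<geneId>.t<i>`, with `mcols` columns `gene_id`, `transcript_id` and
#'   `exons` (an [IRanges::IRangesList] of exon blocks on transcript
#'   coordinates).
#' @export
makeGene <- function(nIsoforms, nExons, exonLenRange = c(40L, 80L),
                     seed = 1L, geneId = "gene1",
                     structure = c("window", "subset")) {
  structure <- match.arg(structure)
  stopifnot(nIsoforms >= 1)
  max_iso <- if (structure == "window")
    1L + nExons * (nExons - 1L) %/% 2L else 2L^nExons - 1L
  if (nIsoforms > max_iso)
    stop("cannot build ", nIsoforms, " distinct isoforms from ",
         nExons, " exons")
  withr::with_seed(seed, {
    lens <- sample(exonLenRange[1]:exonLenRange[2], nExons, replace = TRUE)
    exons <- vapply(lens, .random_seq, character(1))
    subsets <- list(seq_len(nExons))
    while (length(subsets) < nIsoforms) {
      keep <- if (structure == "window") {
        a <- sample.int(nExons - 1L, 1L)
        b <- a + sample.int(nExons - a, 1L)
        a:b
      } else {
        which(runif(nExons) < 0.75)
      }
      if (!length(keep)) next
      if (any(vapply(subsets, identical, logical(1),
                     y = as.integer(keep)))) next
      subsets[[length(subsets) + 1L]] <- as.integer(keep)
    }
    seqs <- vapply(subsets, function(s)
      paste(exons[s], collapse = ""), character(1))
    ids <- paste0(geneId, ".t", seq_along(subsets))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    blocks <- lapply(subsets, function(s) {
      e <- cumsum(lens[s])
      IRanges::IRanges(start = c(1L, e[-length(e)] + 1L), end = e)
    })
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      gene_id = geneId, transcript_id = ids,
      exons = IRanges::IRangesList(blocks))
    out
  })
}

.mutate_seq <- function(bases, errorRate, errorMix) {
  L <- length(bases)
  ev <- which(runif(L) < errorRate)
  n <- c(sub = 0L, ins = 0L, del = 0L)
  out <- bases
  if (length(ev)) {
    type <- sample(3L, length(ev), replace = TRUE, prob = errorMix)
    alphabet <- c("A", "C", "G", "T")
    for (t in seq_along(ev)) {
      i <- ev[t]
      if (type[t] == 1L) {
        out[i] <- sample(setdiff(alphabet, bases[i]), 1L)
      } else if (type[t] == 2L) {
        out[i] <- paste0(bases[i], sample(alphabet, 1L))
      } else {
        out[i] <- ""
      }
    }
    n <- c(sub = sum(type == 1L), ins = sum(type == 2L),
           del = sum(type == 3L))
  }
  list(seq = paste(out, collapse = ""), n = n,
       error_rate = length(ev) / (L + n[["ins"]]))
}

#' Simulate reads from transcripts
#'
#' Each read is its transcript passed through an i.i.d. per-base error
#' process: with probability `errorRate` an event occurs, split among a
#' substitution (to a uniformly drawn different base), a single-base
#' insertion after the position, and a single-base deletion according to
#' `errorMix`. The quality string of a read encodes `errorRate`. The default
#' mix (0.35, 0.30, 0.35) normalizes the substitution/insertion/deletion
#' profile measured on synthetic spike-in data (2.5/2.2/3.0 percent).
#'
#' @param transcripts named [Biostrings::DNAStringSet] or character vector.
#' @param depth integer read count per transcript (recycled).
#' @param errorRate per-base error probability (default 0.07).
#' @param errorMix probabilities of substitution, insertion, deletion.
#' @param seed integer seed.
#' @return list with `sequences` (named [Biostrings::DNAStringSet]),
#'   `errorRate`, and `truth` (data.frame `read_id`, `transcript_id`,
#'   `n_sub`, `n_ins`, `n_del`, `error_rate`, `depth`).
#' @export
simulateReads <- function(transcripts, depth, errorRate = 0.07,
                          errorMix = c(0.35, 0.30, 0.35), seed = 1L) {
  stopifnot(abs(sum(errorMix) - 1) < 1e-9, errorRate >= 0, errorRate < 0.5)
  tseq <- as.character(transcripts)
  tid <- names(tseq)
  if (is.null(tid)) tid <- paste0("t", seq_along(tseq))
  depth <- rep_len(as.integer(depth), length(tseq))
  withr::with_seed(seed, {
    recs <- list()
    for (i in seq_along(tseq)) {
      if (depth[i] < 1L) next
      bases <- strsplit(tseq[i], "", fixed = TRUE)[[1]]
      for (j in seq_len(depth[i])) {
        m <- .mutate_seq(bases, errorRate, errorMix)
        recs[[length(recs) + 1L]] <- list(
          id = paste0(tid[i], "_r", j), seq = m$seq,
          tid = tid[i], n = m$n, er = m$error_rate, depth = depth[i])
      }
    }
    seqs <- Biostrings::DNAStringSet(vapply(recs, `[[`, character(1), "seq"))
    names(seqs) <- vapply(recs, `[[`, character(1), "id")
    truth <- data.frame(
      read_id = names(seqs),
      transcript_id = vapply(recs, `[[`, character(1), "tid"),
      n_sub = vapply(recs, function(r) r$n[["sub"]], integer(1)),
      n_ins = vapply(recs, function(r) r$n[["ins"]], integer(1)),
      n_del = vapply(recs, function(r) r$n[["del"]], integer(1)),
      error_rate = vapply(recs, `[[`, numeric(1), "er"),
      depth = vapply(recs, `[[`, numeric(1), "depth"),
      stringsAsFactors = FALSE)
    list(sequences = seqs, errorRate = errorRate, truth = truth)
  })
}

#' Write a simulation to disk
#'
#' Writes the true transcripts (FASTA), the simulated reads (FASTQ, quality
#' encoding the nominal error rate) and the truth table (TSV with `read_id`,
#' `transcript_id`, `n_sub`, `n_ins`, `n_del`, `error_rate`, `depth`).
#'
#' @param sim result of [simulateReads()].
#' @param transcripts the transcripts the reads were simulated from.
#' @param dir output directory (created if missing).
#' @return invisibly, the three file paths.
#' @export
writeSimulation <- function(sim, transcripts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(transcripts))
    transcripts <- Biostrings::DNAStringSet(transcripts)
  fa <- file.path(dir, "transcripts.fasta")
  fq <- file.path(dir, "reads.fastq")
  tsv <- file.path(dir, "truth.tsv")
  Biostrings::writeXStringSet(transcripts, fa)
  cl <- simToCluster(sim)
  writeFastqReads(cl, fq)
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(transcripts = fa, reads = fq, truth = tsv))
}

#' Build a ReadCluster from simulated reads
#'
#' @param sim result of [simulateReads()].
#' @param clusterId cluster identifier.
#' @return a [ReadCluster-class]; quality probabilities are the uniform
#'   simulated error rate.
#' @export
simToCluster <- function(sim, clusterId = "sim") {
  ReadCluster(sim$sequences, max(sim$errorRate, 1e-6), clusterId)
}
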