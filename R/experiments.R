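# Simulation studies: SNP retention under allele-specific expression,
# exon-deletion overcorrection, and the depth-controlled error-rate curve.

.other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' SNP retention experiment
#'
#' Two identical copies of a random transcript; one copy receives a SNP at a
#' uniformly drawn position within `snpPosRange`. `round(nReads *
#' snpFraction)` reads are simulated from the mutant copy and the rest from
#' the wild type, the cluster is corrected, and a replicate counts as
#' retaining the SNP when at least one corrected read still carries the SNP
#' base at the SNP position (located by alignment to the mutant allele).
#'
#' @param nReads reads per replicate.
#' @param snpFraction fraction of reads from the mutant allele (0, 0.5].
#' @param baseSeqLen transcript length (default 208 nt).
#' @param snpPosRange 1-based range the SNP position is drawn from.
#' @param errorRate per-base error rate (default 0.07).
#' @param replicates number of replicates.
#' @param seed integer seed.
#' @param params a [CorrectionParams-class].
#' @return data.frame per replicate: `replicate`, `n_minor`, `snp_pos`,
#'   `retained`.
#' @export
snpExperiment <- function(nReads, snpFraction, baseSeqLen = 208L,
                          snpPosRange = c(50L, 150L), errorRate = 0.07,
                          replicates = 10L, seed = 1L,
                          params = CorrectionParams()) {
  stopifnot(snpFraction > 0, snpFraction <= 0.5)
  out <- vector("list", replicates)
  for (rep in seq_len(replicates)) {
    s <- .split_seed(seed, rep)
    setup <- withr::with_seed(s, {
      wild <- .random_seq(baseSeqLen)
      pos <- sample(snpPosRange[1]:snpPosRange[2], 1L)
      wb <- substr(wild, pos, pos)
      mb <- .other_base(wb)
      mut <- wild
      substr(mut, pos, pos) <- mb
      nMinor <- round(nReads * snpFraction)
      origin <- rep("wild", nReads)
      origin[sample(nReads, nMinor)] <- "mut"
      list(wild = wild, mut = mut, pos = pos, mb = mb, origin = origin,
           nMinor = nMinor)
    })
    tx <- c(wild = setup$wild, mut = setup$mut)
    sim <- simulateReads(tx[setup$origin], depth = 1L,
                         errorRate = errorRate, seed = .split_seed(s, 1L))
    names(sim$sequences) <- paste0("r", seq_len(nReads))
    cl <- simToCluster(sim, "snp")
    cc <- correctCluster(cl, params)
    corr <- as.character(readSequences(cc))
    carries <- vapply(corr, function(x)
      .cpp_aligned_base_at(x, setup$mut, setup$pos - 1L) == setup$mb,
      logical(1), USE.NAMES = FALSE)
    out[[rep]] <- data.frame(replicate = rep, n_minor = setup$nMinor,
                             snp_pos = setup$pos, retained = any(carries))
  }
  do.call(rbind, out)
}

#' Exon-deletion overcorrection experiment
#'
#' Two copies of a random transcript; one copy loses a substring of
#' `deletionLen` nucleotides at a random position. One of the two isoforms
#' (chosen at random) is the minor isoform with fraction `minorFraction` of
#' the reads. Reads are assigned to the isoform with the strictly smaller
#' edit distance (ties assigned to neither) before and after correction.
#'
#' @param deletionLen deleted exon length (e.g. 5, 10 or 20).
#' @param nReads reads per replicate.
#' @param minorFraction fraction of reads from the minor isoform.
#' @param baseSeqLen transcript length.
#' @param posRange 1-based range of the deletion start.
#' @param errorRate per-base error rate.
#' @param replicates number of replicates.
#' @param seed integer seed.
#' @param params a [CorrectionParams-class].
#' @return data.frame per replicate: `replicate`, `minor_is_deleted`,
#'   `frac_before`, `frac_after`.
#' @export
exonExperiment <- function(deletionLen, nReads, minorFraction,
                           baseSeqLen = 208L, posRange = c(50L, 150L),
                           errorRate = 0.07, replicates = 10L, seed = 1L,
                           params = CorrectionParams()) {
  frac_minor <- function(seqs, isoA, isoB, minor) {
    edA <- vapply(seqs, function(x) .cpp_edit_distance(x, isoA), integer(1))
    edB <- vapply(seqs, function(x) .cpp_edit_distance(x, isoB), integer(1))
    toA <- edA < edB
    toB <- edB < edA
    n_assigned <- sum(toA) + sum(toB)
    if (n_assigned == 0L) return(NA_real_)
    (if (minor == "A") sum(toA) else sum(toB)) / n_assigned
  }
  out <- vector("list", replicates)
  for (rep in seq_len(replicates)) {
    s <- .split_seed(seed, 1000L + rep)
    setup <- withr::with_seed(s, {
      isoA <- .random_seq(baseSeqLen)
      pos <- sample(posRange[1]:posRange[2], 1L)
      isoB <- paste0(substr(isoA, 1L, pos - 1L),
                     substr(isoA, pos + deletionLen, baseSeqLen))
      minor <- sample(c("A", "B"), 1L)
      nMinor <- round(nReads * minorFraction)
      origin <- rep(setdiff(c("A", "B"), minor), nReads)
      origin[sample(nReads, nMinor)] <- minor
      list(isoA = isoA, isoB = isoB, minor = minor, origin = origin)
    })
    tx <- c(A = setup$isoA, B = setup$isoB)
    sim <- simulateReads(tx[setup$origin], depth = 1L,
                         errorRate = errorRate, seed = .split_seed(s, 1L))
    names(sim$sequences) <- paste0("r", seq_len(nReads))
    cl <- simToCluster(sim, "exon")
    cc <- correctCluster(cl, params)
    out[[rep]] <- data.frame(
      replicate = rep,
      minor_is_deleted = setup$minor == "B",
      frac_before = frac_minor(as.character(sim$sequences),
                               setup$isoA, setup$isoB, setup$minor),
      frac_after = frac_minor(as.character(readSequences(cc)),
                              setup$isoA, setup$isoB, setup$minor))
  }
  do.call(rbind, out)
}

#' Depth-controlled correction experiment
#'
#' Generates genes with exon-sharing isoforms, assigns every transcript a
#' read depth drawn log-uniformly from `[1, maxDepth]` (the broad dynamic
#' range typical of expression data), simulates reads at `errorRate`,
#' corrects each gene cluster, and evaluates per-read error rates against
#' the known transcripts of the gene.
#'
#' @param nGenes number of genes (one cluster each).
#' @param isoformsPerGene isoforms per gene, recycled across genes; the
#'   default mix (1 to 4) emulates gene families in which some genes express
#'   a single isoform and others several overlapping ones.
#' @param nExons exons per gene.
#' @param exonLenRange exon length range.
#' @param maxDepth largest per-transcript depth.
#' @param errorRate per-base error rate.
#' @param seed integer seed.
#' @param params a [CorrectionParams-class].
#' @return list with `perRead` (pooled evaluator output across genes) and
#'   `summary` (medians and fractions by true transcript depth).
#' @export
depthExperiment <- function(nGenes = 50L,
                            isoformsPerGene = c(1L, 2L, 3L, 4L, 3L, 2L),
                            nExons = 6L,
                            exonLenRange = c(120L, 220L), maxDepth = 50L,
                            errorRate = 0.07, seed = 1L,
                            params = CorrectionParams()) {
  niso <- rep_len(as.integer(isoformsPerGene), nGenes)
  per <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    sg <- .split_seed(seed, 10000L + g)
    tx <- makeGene(niso[g], nExons, exonLenRange, seed = sg,
                   geneId = paste0("g", g))
    depths <- withr::with_seed(.split_seed(sg, 1L), {
      pmax(1L, as.integer(round(exp(runif(length(tx), 0,
                                          log(maxDepth))))))
    })
    sim <- simulateReads(tx, depths, errorRate = errorRate,
                         seed = .split_seed(sg, 2L))
    if (!length(sim$sequences)) next
    cl <- simToCluster(sim, paste0("g", g))
    cc <- correctCluster(cl, params)
    ev <- evaluateCorrection(cc, cl, sim$truth, tx)
    per[[g]] <- ev$perRead
  }
  perRead <- do.call(rbind, per)
  spl <- split(seq_len(nrow(perRead)), perRead$depth)
  summary <- data.frame(
    depth = as.numeric(names(spl)),
    n = lengths(spl),
    median_before = vapply(spl, function(ii)
      median(perRead$err_before[ii]), numeric(1)),
    median_after = vapply(spl, function(ii)
      median(perRead$err_after[ii]), numeric(1)),
    frac_miscorrected = vapply(spl, function(ii)
      mean(perRead$miscorrected[ii]), numeric(1)),
    frac_overcorrected = vapply(spl, function(ii)
      mean(perRead$overcorrected[ii]), numeric(1)),
    row.names = NULL)
  list(perRead = perRead, summary = summary)
}
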