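# Synthetic gene/read generation and the evaluation harness.

test_that("makeGene builds distinct exon-sharing isoforms deterministically", {
  g1 <- makeGene(1, 4, c(30, 50), seed = 7)
  expect_equal(length(g1), 1L)
  ex <- S4Vectors::mcols(g1)$exons[[1]]
  expect_equal(sum(IRanges::width(ex)), Biostrings::width(g1)[1])
  expect_equal(min(IRanges::start(ex)), 1L)  # blocks tile the transcript
  expect_true(all(IRanges::start(ex)[-1] ==
                    IRanges::end(ex)[-length(ex)] + 1L))

  g <- makeGene(3, 5, c(30, 50), seed = 8)
  expect_equal(length(g), 3L)
  seqs <- as.character(g)
  expect_equal(anyDuplicated(seqs), 0L)
  # every isoform shares sequence with the full first isoform
  expect_true(all(vapply(seqs[-1], function(s)
    grepl(substr(s, 1, 30), seqs[1], fixed = TRUE) ||
      nchar(s) < nchar(seqs[1]), logical(1))))
  g2 <- makeGene(3, 5, c(30, 50), seed = 8)
  expect_identical(as.character(g), as.character(g2))  # same seed
  expect_error(makeGene(40, 3, c(30, 50), seed = 1), "cannot build")
})

test_that("error-free simulation reproduces the transcripts", {
  g <- makeGene(2, 4, c(30, 50), seed = 9)
  sim <- simulateReads(g, depth = 3, errorRate = 0, seed = 10)
  expect_equal(nrow(sim$truth), 6L)
  expect_true(all(sim$truth$error_rate == 0))
  expect_equal(as.character(sim$sequences[1]),
               as.character(g[[1]]), ignore_attr = TRUE)
})

test_that("realized error rates concentrate around the nominal rate", {
  tx <- setNames(withr::with_seed(11, random_seq(1000)), "t")
  sim <- simulateReads(tx, depth = 10, errorRate = 0.07, seed = 12)
  n_events <- with(sim$truth, n_sub + n_ins + n_del)
  # binomial concentration: total events within 3 sd of 10000 * 0.07
  expect_lt(abs(sum(n_events) - 700), 3 * sqrt(10000 * 0.07 * 0.93))
  # error mix close to (0.35, 0.30, 0.35)
  mix <- c(sum(sim$truth$n_sub), sum(sim$truth$n_ins),
           sum(sim$truth$n_del)) / sum(n_events)
  expect_lt(max(abs(mix - c(0.35, 0.30, 0.35))), 0.06)
})

test_that("the evaluator computes exact rates on constructed cases", {
  tx <- c(t1 = withr::with_seed(13, random_seq(200)))
  # e isolated substitutions on length L: error rate exactly e/L
  mutated <- tx[["t1"]]
  pos <- c(20, 60, 110, 160)
  for (p in pos) substr(mutated, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(mutated, p, p))[1]
  truth <- data.frame(read_id = "r1", transcript_id = "t1")
  ev <- evaluateCorrection(c(r1 = tx[["t1"]]), c(r1 = mutated), truth, tx)
  expect_equal(ev$perRead$err_before, 4 / 200)
  expect_equal(ev$perRead$err_after, 0)
  expect_false(ev$perRead$miscorrected)
  expect_false(ev$perRead$overcorrected)
  expect_equal(ev$perRead$overcorrection_distance, 0)
  # corrected into the WRONG transcript: overcorrected, distance = ed(true)
  tx2 <- c(tx, t2 = withr::with_seed(14, random_seq(200)))
  ev2 <- evaluateCorrection(c(r1 = tx2[["t2"]]), c(r1 = mutated),
                            truth, tx2)
  expect_true(ev2$perRead$overcorrected)
  expect_equal(ev2$perRead$overcorrection_distance,
               editDistance(tx2[["t2"]], tx2[["t1"]]))
  # a corrected read with MORE mismatches than before is miscorrected
  worse <- mutated
  for (p in c(30, 80, 130, 170, 190)) substr(worse, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(worse, p, p))[1]
  ev3 <- evaluateCorrection(c(r1 = worse), c(r1 = mutated), truth, tx)
  expect_true(ev3$perRead$miscorrected)
  expect_error(evaluateCorrection(c(rX = tx[["t1"]]), c(r1 = mutated),
                                  truth, tx), "identifiers")
})

test_that("evaluator metrics equal an independently scripted alignment", {
  withr::with_seed(15, {
    tx <- c(t1 = random_seq(150))
    for (i in 1:10) {
      sim <- simulateReads(tx, 1, errorRate = 0.08, seed = 100 + i)
      read <- unname(as.character(sim$sequences)[1])
      st <- align_stats_oracle(read, tx[["t1"]])
      truth <- data.frame(read_id = "r", transcript_id = "t1")
      ev <- evaluateCorrection(c(r = read), c(r = read), truth, tx)
      expect_equal(ev$perRead$err_before,
                   sum(st[c("subs", "ins", "del")]) / sum(st))
    }
  })
})

test_that("simulation and evaluation round-trip through their file formats", {
  g <- makeGene(2, 4, c(30, 50), seed = 30)
  sim <- simulateReads(g, depth = 2, errorRate = 0.05, seed = 31)
  d <- tempfile()
  paths <- writeSimulation(sim, g, d)
  expect_true(all(file.exists(paths)))
  back <- readFastqCluster(paths[["reads"]])
  expect_equal(names(back), sim$truth$read_id)
  truth <- utils::read.delim(paths[["truth"]])
  expect_equal(truth$transcript_id, sim$truth$transcript_id)
  tx_back <- Biostrings::readDNAStringSet(paths[["transcripts"]])
  ev <- evaluateCorrection(back, back, truth, tx_back)
  expect_equal(nrow(ev$perRead), 4L)
  ep <- writeEvaluation(ev, d)
  expect_equal(nrow(utils::read.delim(ep[["metrics"]])), 4L)
  expect_true(file.exists(ep[["summary"]]))
})

test_that("SNP experiment retains everything without sequencing errors", {
  r <- snpExperiment(nReads = 12, snpFraction = 0.5, errorRate = 1e-6,
                     replicates = 3, seed = 16)
  expect_true(all(r$retained))
  expect_equal(r$n_minor, rep(6, 3))
  expect_true(all(r$snp_pos >= 50 & r$snp_pos <= 150))
})

test_that("exon experiment leaves fractions unchanged without errors", {
  r <- exonExperiment(deletionLen = 20, nReads = 12, minorFraction = 0.25,
                      errorRate = 1e-6, replicates = 3, seed = 17)
  expect_equal(r$frac_before, rep(0.25, 3))
  expect_equal(r$frac_after, r$frac_before)
})

test_that("large exon deletions are preserved, tiny ones overcorrected", {
  r20 <- exonExperiment(deletionLen = 20, nReads = 30, minorFraction = 0.3,
                        replicates = 5, seed = 18)
  expect_gt(mean(r20$frac_after), 0.7 * mean(r20$frac_before))
  r5 <- exonExperiment(deletionLen = 5, nReads = 30, minorFraction = 0.3,
                       replicates = 5, seed = 18)
  expect_lt(mean(r5$frac_after), mean(r5$frac_before))
})
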