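# Whole-read and whole-cluster correction, modes, batching and the CLI.

test_that("identical error-free reads are a fixpoint in both modes", {
  s <- withr::with_seed(22, random_seq(200))
  cl <- ReadCluster(setNames(rep(s, 12), paste0("r", 1:12)), 1e-3, "c")
  for (mode in c("exact", "approximate")) {
    cc <- correctCluster(cl, CorrectionParams(mode = mode))
    expect_equal(as.character(readSequences(cc)), rep(s, 12),
                 ignore_attr = TRUE)
  }
})

test_that("reads without anchor pairs are returned unchanged", {
  # too short for any pair at xmin = 2k
  cl <- ReadCluster(c(a = "ACGTACGTACGT", b = "ACGTACGTACGT"), 0.07, "c")
  cc <- correctCluster(cl)
  expect_equal(unname(as.character(readSequences(cc))[1]), "ACGTACGTACGT")
  expect_equal(attr(cc, "run")$n_no_anchors, 2L)
  # a lone unrelated read keeps support 1 and is conserved everywhere
  sc <- sim_cluster(n = 1, len = 250, seed = 23)
  cc1 <- correctCluster(ReadCluster(
    c(readSequences(sc$cluster),
      Biostrings::DNAStringSet(c(other = random_seq(250)))), 0.07, "c"))
  expect_equal(as.character(readSequences(cc1))[1],
               as.character(readSequences(sc$cluster))[1])
})

test_that("correction reduces the error rate of simulated reads", {
  sc <- sim_cluster(n = 20, len = 300, seed = 24)
  cc <- correctCluster(sc$cluster)
  ev <- evaluateCorrection(cc, sc$cluster, sc$sim$truth, sc$tx)
  expect_lt(median(ev$perRead$err_after), median(ev$perRead$err_before))
  expect_lt(median(ev$perRead$err_after), 0.02)
  expect_equal(attr(cc, "run")$mode, "exact")  # 20 < 50 reads
})

test_that("runs are deterministic and preserve ids and read counts", {
  sc <- sim_cluster(n = 15, len = 250, seed = 25)
  c1 <- correctCluster(sc$cluster)
  c2 <- correctCluster(sc$cluster)
  expect_identical(as.character(readSequences(c1)),
                   as.character(readSequences(c2)))
  expect_equal(names(c1), names(sc$cluster))
  expect_equal(length(c1), length(sc$cluster))
})

test_that("sequence outside selected intervals is conserved", {
  sc <- sim_cluster(n = 10, len = 300, seed = 26)
  rid <- names(sc$cluster)[1]
  res <- correctRead(sc$cluster, rid)
  orig <- as.character(readSequences(sc$cluster))[1]
  iv <- res$intervals
  expect_true(nrow(iv) >= 1)
  # prefix before the first interval and suffix after the last, including
  # the bounding anchor k-mers, are untouched
  expect_equal(substr(res$sequence, 1, iv$begin[1]),
               unname(substr(orig, 1, iv$begin[1])))
  tail_len <- nchar(orig) - iv$end[nrow(iv)]
  expect_equal(substr(res$sequence, nchar(res$sequence) - tail_len + 1,
                      nchar(res$sequence)),
               unname(substr(orig, iv$end[nrow(iv)] + 1, nchar(orig))))
  # intervals are pairwise disjoint and ordered
  if (nrow(iv) > 1) expect_true(all(iv$begin[-1] >= iv$end[-nrow(iv)]))
})

test_that("exact and approximate modes agree within the correction gain", {
  sc <- sim_cluster(n = 30, len = 300, seed = 27)
  ce <- correctCluster(sc$cluster, CorrectionParams(mode = "exact"))
  ca <- correctCluster(sc$cluster, CorrectionParams(mode = "approximate"))
  ee <- evaluateCorrection(ce, sc$cluster, sc$sim$truth, sc$tx)$perRead
  ea <- evaluateCorrection(ca, sc$cluster, sc$sim$truth, sc$tx)$perRead
  pre <- median(ee$err_before)
  gain <- pre - max(median(ee$err_after), median(ea$err_after))
  expect_gt(gain, 0)
  expect_lt(abs(median(ee$err_after) - median(ea$err_after)), 0.5 * gain)
})

test_that("cluster mode selection and batching follow the parameters", {
  s <- withr::with_seed(28, random_seq(60))
  big <- ReadCluster(setNames(rep(s, 1200), paste0("r", 1:1200)), 1e-3, "c")
  par <- CorrectionParams()
  expect_equal(AnchorCorrect:::.resolve_mode(par, 40), "exact")
  expect_equal(AnchorCorrect:::.resolve_mode(par, 50), "approximate")
  cc <- correctCluster(big, par)
  run <- attr(cc, "run")
  expect_equal(run$mode, "approximate")
  expect_equal(run$n_batches, 2L)  # 1000 + 200
  expect_equal(run$w, adaptiveWindow(1200, 9))
  expect_equal(as.character(readSequences(cc)), rep(s, 1200),
               ignore_attr = TRUE)
})

test_that("the CLI corrects files and honors parameter flags", {
  d <- tempfile(); dir.create(d)
  sc <- sim_cluster(n = 8, len = 200, seed = 29)
  writeFastqReads(sc$cluster, file.path(d, "c1.fastq"))
  out <- file.path(d, "out")
  status <- runCorrectCLI(c("--fastq", file.path(d, "c1.fastq"),
                            "--outfolder", out))
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "corrected.fastq")))
  res <- readFastqCluster(file.path(out, "corrected.fastq"))
  expect_equal(names(res), names(sc$cluster))
  expect_true(file.exists(file.path(out, "run.log")))
  # per-cluster directory input with a fixed window
  ind <- file.path(d, "clusters"); dir.create(ind)
  writeFastqReads(sc$cluster, file.path(ind, "g1.fastq"))
  writeFastqReads(sc$cluster, file.path(ind, "g2.fastq"))
  out2 <- file.path(d, "out2")
  status <- runCorrectCLI(c("--indir", ind, "--outfolder", out2,
                            "--k", "9", "--xmax", "80", "--T", "0.1",
                            "--set_w_dynamically", "FALSE", "--w", "10"))
  expect_equal(status, 0L)
  expect_true(all(file.exists(file.path(out2, c("g1.fastq", "g2.fastq")))))
  expect_true(any(grepl("w=10", readLines(file.path(out2, "run.log")))))
  # missing input is a nonzero status
  expect_equal(suppressMessages(runCorrectCLI(c("--outfolder", out))), 1L)
})
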