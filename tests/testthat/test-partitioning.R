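# Edit distance, quality-aware similarity, interval support and the
# weighted interval scheduling solver.

test_that("edit distance equals independent oracles", {
  expect_equal(editDistance("kitten", "sitting"), 3L)
  expect_equal(editDistance("", "ACGT"), 4L)
  withr::with_seed(5, {
    for (i in 1:40) {
      a <- random_seq(sample(1:140, 1))
      b <- random_seq(sample(1:140, 1))
      expect_equal(editDistance(a, b),
                   as.integer(utils::adist(a, b)))
    }
    # a few against the hand-written DP, including > 64 nt (multi-word)
    for (i in 1:5) {
      a <- random_seq(90); b <- random_seq(85)
      expect_equal(editDistance(a, b), ed_oracle(a, b))
    }
  })
})

test_that("global alignment reproduces sequences and its cost is optimal", {
  withr::with_seed(6, {
    for (i in 1:15) {
      a <- random_seq(40); b <- random_seq(35)
      al <- globalAlign(a, b)
      expect_equal(gsub("-", "", al[1]), a)
      expect_equal(gsub("-", "", al[2]), b)
      cost <- sum(strsplit(al[1], "")[[1]] != strsplit(al[2], "")[[1]])
      expect_equal(cost, editDistance(a, b))
    }
  })
})

test_that("similarity uses the strict quality threshold", {
  expect_true(isSimilar("ACGTACGT", "ACGTACGT", 0.01, 0.01))
  withr::with_seed(7, {
    s <- random_seq(100)
    # plant substitutions at distinct positions, verify the exact boundary
    mutate_n <- function(s, n) {
      pos <- sample(100, n)
      ch <- strsplit(s, "")[[1]]
      for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
      paste(ch, collapse = "")
    }
    s13 <- mutate_n(s, 13)
    s14 <- mutate_n(s, 14)
    # substitutions at distinct positions; oracle confirms realized distance
    if (ed_oracle(s, s13) == 13)
      expect_true(isSimilar(s, s13, 0.07, 0.07))
    if (ed_oracle(s, s14) == 14)
      expect_false(isSimilar(s, s14, 0.07, 0.07))  # 14 < 14 fails
  })
})

test_that("support counts similar occurrences with self included", {
  s <- withr::with_seed(8, random_seq(80))
  par <- CorrectionParams(k = 5L, xmin = 10L, xmax = 40L)
  cl3 <- ReadCluster(setNames(rep(s, 3), paste0("r", 1:3)), 0.05, "c")
  idx <- buildPairIndex(cl3, par)
  occ <- idx[[5]]
  sup <- computeSupport(cl3, occ$read_id[1], occ$p[1], occ$q[1], par)
  expect_equal(sup$support, 3L)
  expect_equal(nrow(sup$segments), 3L)
  expect_equal(sup$weight, 3 * (occ$q[1] - occ$p[1] - 5))
  # cluster of one read: self only
  sup1 <- computeSupport(cl3[1], occ$read_id[1], occ$p[1], occ$q[1], par)
  expect_equal(sup1$support, 1L)
  expect_error(computeSupport(cl3, "r1", 1, 2, par), "not found")
})

test_that("only the smallest-edit-distance occurrence per read counts", {
  # r2 carries the anchor pair twice: once nearly identical to r1's span,
  # once with a corrupted middle
  withr::with_seed(9, {
    left <- random_seq(6); right <- random_seq(6)
    mid_good <- random_seq(14)
  })
  mid_bad <- paste(rev(strsplit(mid_good, "")[[1]]), collapse = "")
  r1 <- paste0("GG", left, mid_good, right, "GG")
  r2 <- paste0(left, mid_good, right, "TT", left, mid_bad, right)
  par <- CorrectionParams(k = 6L, xmin = 12L, xmax = 30L)
  cl <- ReadCluster(c(r1 = r1, r2 = r2), 0.10, "c")
  sup <- computeSupport(cl, "r1", 2, 2 + 6 + 14, par)
  expect_equal(sup$support, 2L)  # self + the good copy, counted once
  expect_equal(sup$segments$start[2], 0)
})

test_that("removing a read never increases support", {
  sc <- sim_cluster(n = 8, len = 150, seed = 33)
  par <- CorrectionParams()
  idx <- buildPairIndex(sc$cluster, par)
  key <- which(vapply(idx, nrow, integer(1)) >= 4)[1]
  occ <- idx[[key]]
  full <- computeSupport(sc$cluster, occ$read_id[1], occ$p[1], occ$q[1], par)
  keep <- setdiff(names(sc$cluster), setdiff(names(sc$cluster),
                                             occ$read_id[1])[1])
  sub <- computeSupport(sc$cluster[keep], occ$read_id[1], occ$p[1],
                        occ$q[1], par)
  expect_lte(sub$support, full$support)
})

test_that("interval scheduling picks the optimal non-overlapping subset", {
  iv <- data.frame(begin = c(0, 20), end = c(10, 35), weight = c(5, 5))
  expect_equal(nrow(solveIntervalScheduling(iv)), 2L)  # disjoint: take both
  iv <- data.frame(begin = c(0, 10, 0), end = c(10, 20, 20),
                   weight = c(5, 5, 9))
  sel <- solveIntervalScheduling(iv)
  expect_equal(sum(sel$weight), 10)  # two abutting 5s beat the 9
  expect_equal(sel$begin, c(0, 10))
  # abutting half-open intervals are compatible
  iv <- data.frame(begin = c(0, 10), end = c(10, 20), weight = c(1, 1))
  expect_equal(nrow(solveIntervalScheduling(iv)), 2L)
})

test_that("scheduling equals the exhaustive optimum on random instances", {
  withr::with_seed(10, {
    for (i in 1:200) {
      n <- sample(4:12, 1)
      begin <- sample(0:50, n, replace = TRUE)
      len <- sample(1:20, n, replace = TRUE)
      iv <- data.frame(begin = begin, end = begin + len,
                       weight = round(runif(n, 0.5, 30), 2))
      sel <- solveIntervalScheduling(iv)
      expect_true(all(sel$begin[-1] >= sel$end[-nrow(sel)]))
      expect_equal(sum(sel$weight),
                   wis_oracle(iv$begin, iv$end, iv$weight))
    }
  })
})
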