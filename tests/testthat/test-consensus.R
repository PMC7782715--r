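# Homopolymer compression, POA consensus, alignment matrix, trusted
# variants and row correction.

test_that("homopolymer compression collapses runs and is idempotent", {
  expect_equal(hcCompress("ATTTCAA"), "ATCA")
  expect_equal(hcCompress(""), "")
  withr::with_seed(12, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE,
                        prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
      expect_equal(hcCompress(hcCompress(s)), hcCompress(s))
    }
  })
})

test_that("consensus recovers unanimity and simple majorities", {
  s <- withr::with_seed(13, random_seq(60))
  expect_equal(buildConsensus(rep(s, 5)), s)
  mut <- s
  substr(mut, 30, 30) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, 30, 30))[1]
  expect_equal(buildConsensus(c(rep(s, 10), mut)), s)
  # single-base insertion in a minority of segments
  ins <- paste0(substr(s, 1, 20), "G", substr(s, 21, 60))
  expect_equal(buildConsensus(c(rep(s, 8), ins, ins)), s)
  expect_error(buildConsensus(character(0)), "segments")
})

test_that("only the first maxSeqToSpoa segments enter the consensus", {
  s <- withr::with_seed(14, random_seq(40))
  other <- withr::with_seed(15, random_seq(40))
  segs <- c(rep(s, 200), rep(other, 100))
  expect_equal(buildConsensus(segs, maxSeqToSpoa = 200L), s)
})

test_that("the alignment matrix encodes deletions and insertions", {
  cons <- "ACGTACGTAC"
  m <- buildMatrix(rep(cons, 4), cons)
  expect_true(all(m$rows == cons))
  expect_equal(m$consensusRow, cons)
  # one deletion
  m <- buildMatrix(c(cons, "ACGTCGTAC"), cons)
  expect_equal(nchar(m$rows[1]), nchar(m$consensusRow))
  expect_equal(gsub("-", "", m$rows[2]), "ACGTCGTAC")
  expect_equal(sum(strsplit(m$rows[2], "")[[1]] == "-"), 1L)
  # one insertion opens an all-gap consensus column
  m <- buildMatrix(c(cons, "ACGTTTACGTAC"), cons)
  expect_equal(sum(strsplit(m$consensusRow, "")[[1]] == "-"), 2L)
  expect_equal(gsub("-", "", m$rows[2]), "ACGTTTACGTAC")
  expect_equal(gsub("-", "", m$consensusRow), cons)
})

test_that("rows always reproduce their segments after degapping", {
  withr::with_seed(16, {
    cons <- random_seq(50)
    segs <- vapply(1:8, function(i) {
      sc <- sim_cluster(n = 1, len = 50, seed = i + 100)
      as.character(readSequences(sc$cluster))[1]
    }, character(1))
    m <- buildMatrix(segs, cons)
    expect_equal(gsub("-", "", m$rows), segs, ignore_attr = TRUE)
    expect_true(all(nchar(m$rows) == nchar(m$consensusRow)))
  })
})

test_that("trustedThreshold follows the printed formula", {
  ctx <- "ACGTACGTA"
  snp <- "ACGTCCGTA"  # isolated substitution: both distances 1
  expect_equal(trustedThreshold(30, 0.1, ctx, snp), 3)       # max(3, 3)
  expect_equal(trustedThreshold(100, 0.1, ctx, snp), 10)     # 100*0.1/1
  two <- "ACCTCCGTA"  # two substitutions
  expect_equal(trustedThreshold(100, 0.1, ctx, two), 5)      # max(3, 5)
  expect_equal(trustedThreshold(10, 0.1, ctx, two), 3)       # floor of 3
  # homopolymer-length-only difference is not considered
  expect_true(is.na(trustedThreshold(50, 0.1, "ACCCG", "ACCG")))
  # gap symbols are stripped before the distances
  expect_equal(trustedThreshold(30, 0.1, "AC-GTACGTA", "ACG-TCCGTA"),
               trustedThreshold(30, 0.1, "ACGTACGTA", "ACGTCCGTA"))
})

test_that("trusted sets require three rows and the threshold", {
  mk_rows <- function(m, c_minor, width = 21L, snp_col = 11L) {
    base <- withr::with_seed(17, random_seq(width))
    minor <- base
    substr(minor, snp_col, snp_col) <-
      setdiff(c("A", "C", "G", "T"), substr(base, snp_col, snp_col))[1]
    list(rows = c(rep(minor, c_minor), rep(base, m - c_minor)),
         cons = base, minor = minor)
  }
  x <- mk_rows(10, 0)
  tr <- trustedSets(x$rows, x$cons, k = 9, T = 0.1)
  expect_true(all(vapply(tr, nrow, integer(1)) == 1L))  # consensus only
  x <- mk_rows(30, 3)
  tr <- trustedSets(x$rows, x$cons, k = 9, T = 0.1)
  expect_equal(nrow(tr[[11]]), 2L)  # SNP context trusted: 3 >= max(3, 3)
  x <- mk_rows(30, 2)
  tr <- trustedSets(x$rows, x$cons, k = 9, T = 0.1)
  expect_equal(nrow(tr[[11]]), 1L)  # 2 < 3: not trusted
})

test_that("row correction fixes errors and retains supported variants", {
  s <- withr::with_seed(18, random_seq(40))
  segs <- rep(s, 30)
  err <- s
  substr(err, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                 substr(s, 20, 20))[1]
  m <- buildMatrix(c(err, segs), s)
  fixed <- correctRow(m$rows, m$consensusRow, rowIndex = 1L)
  expect_equal(fixed, s)  # lone error corrected to consensus
  clean <- correctRow(m$rows, m$consensusRow, rowIndex = 2L)
  expect_equal(clean, s)  # error-free row unchanged
  # a 3-supported SNP survives: its own context is trusted at distance 0
  m2 <- buildMatrix(c(rep(err, 3), rep(s, 27)), s)
  kept <- correctRow(m2$rows, m2$consensusRow, rowIndex = 1L)
  expect_equal(kept, err)
})

test_that("SNP retention matches the analytic rule across m and c", {
  base <- withr::with_seed(19, random_seq(25))
  minor <- base
  # a truly isolated SNP: the new base differs from both neighbors, so the
  # variant is not a homopolymer-length change (which would be discarded)
  substr(minor, 13, 13) <- setdiff(c("A", "C", "G", "T"),
                                   substring(base, 12:14, 12:14))[1]
  for (m in seq(10, 100, by = 10)) {
    for (cc in unique(pmin(m, c(1, 2, 3, ceiling(0.1 * m) + c(-1, 0, 1))))) {
      if (cc < 0) next
      rows <- c(rep(minor, cc), rep(base, m - cc))
      got <- correctRow(rows, base, rowIndex = 1L)
      retained <- got == minor
      expect_equal(retained, cc >= max(3, 0.1 * m),
                   info = sprintf("m=%d c=%d", m, cc))
    }
  }
})

test_that("homopolymer-length-only rows are corrected to the consensus", {
  base <- "ACGTACCCGTACGTACGACT"
  extra <- "ACGTACCCCGTACGTACGACT"  # one extra C in the run
  m <- buildMatrix(c(rep(extra, 5), rep(base, 15)), base)
  fixed <- correctRow(m$rows, m$consensusRow, rowIndex = 1L)
  expect_equal(fixed, base)
})
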