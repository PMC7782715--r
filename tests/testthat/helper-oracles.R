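# Independent oracles used across the test files. These are deliberately
# naive second implementations (plain R dynamic programs and exhaustive
# enumerations), kept separate from the package's C++ code paths.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# textbook Levenshtein DP
ed_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  prev <- 0:length(B)
  for (i in seq_along(A)) {
    cur <- c(i, numeric(length(B)))
    for (j in seq_along(B))
      cur[j + 1] <- min(prev[j] + (A[i] != B[j]), prev[j + 1] + 1,
                        cur[j] + 1)
    prev <- cur
  }
  prev[length(B) + 1]
}

# exhaustive weighted-interval-scheduling optimum over all subsets
wis_oracle <- function(begin, end, weight) {
  n <- length(begin)
  masks <- 0:(2^n - 1)
  total <- numeric(length(masks))
  ok <- rep(TRUE, length(masks))
  for (i in seq_len(n)) {
    has_i <- bitwAnd(masks, bitwShiftL(1L, i - 1L)) != 0L
    total[has_i] <- total[has_i] + weight[i]
    conflict <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      if (min(end[i], end[j]) > max(begin[i], begin[j]))
        conflict <- bitwOr(conflict, bitwShiftL(1L, j - 1L))
    }
    ok[has_i & bitwAnd(masks, conflict) != 0L] <- FALSE
  }
  max(total[ok])
}

# naive per-window minimizer scan (leftmost smallest k-mer per window)
minimizer_oracle <- function(seq, k, w) {
  L <- nchar(seq)
  if (L < k) return(integer(0))
  starts <- 0:(L - k)
  kmers <- substring(seq, starts + 1, starts + k)
  picked <- integer(0)
  for (p in 0:(L - k)) {
    win <- starts[starts >= p & starts <= min(p + w - k, L - k)]
    km <- kmers[win + 1]
    best <- win[which(km == min(km))[1]]
    if (!length(picked) || picked[length(picked)] != best)
      picked <- c(picked, best)
  }
  picked
}

# plain-R unit-cost alignment statistics (same tie preference as the
# package: diagonal, then gap in reference, then gap in read)
align_stats_oracle <- function(read, ref) {
  A <- strsplit(read, "")[[1]]
  B <- strsplit(ref, "")[[1]]
  n <- length(A); m <- length(B)
  D <- matrix(0L, n + 1, m + 1)
  D[1, ] <- 0:m
  D[, 1] <- 0:n
  TB <- matrix(2L, n + 1, m + 1)  # 0 diag, 1 up, 2 left
  TB[, 1] <- 1L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    diag <- D[i, j] + (A[i] != B[j])
    up <- D[i, j + 1] + 1L
    left <- D[i + 1, j] + 1L
    best <- diag; t <- 0L
    if (up < best) { best <- up; t <- 1L }
    if (left < best) { best <- left; t <- 2L }
    D[i + 1, j + 1] <- best
    TB[i + 1, j + 1] <- t
  }
  i <- n; j <- m
  st <- c(matches = 0L, subs = 0L, ins = 0L, del = 0L)
  while (i > 0 || j > 0) {
    t <- TB[i + 1, j + 1]
    if (i > 0 && j > 0 && t == 0L) {
      st[if (A[i] == B[j]) "matches" else "subs"] <-
        st[if (A[i] == B[j]) "matches" else "subs"] + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && (t == 1L || j == 0)) {
      st["ins"] <- st["ins"] + 1L
      i <- i - 1
    } else {
      st["del"] <- st["del"] + 1L
      j <- j - 1
    }
  }
  st
}

# small simulated single-transcript cluster used by several tests
sim_cluster <- function(n = 10, len = 300, errorRate = 0.07, seed = 1) {
  tx <- withr::with_seed(seed, random_seq(len))
  sim <- simulateReads(setNames(tx, "t1"), depth = n,
                       errorRate = errorRate, seed = seed + 1)
  list(tx = c(t1 = tx), sim = sim, cluster = simToCluster(sim))
}
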