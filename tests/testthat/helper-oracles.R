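# Independent oracles, deliberately naive: a pure-R affine-gap local
# alignment DP, exhaustive modularity maximization over all partitions,
# and O(n^2) pairwise interval overlap checking. These never call the
# package's alignment or graph code.

# Smith-Waterman with affine gaps; a gap of length L costs open + L*ext.
# Returns only the optimal score.
swOracleScore <- function(a, b, submat, open, ext) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)     # gap in b (deletion from a)
  Y <- matrix(NEG, n + 1, m + 1)     # gap in a
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                Y[i - 1, j - 1]))
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# all set partitions of 1..n (restricted growth strings)
allPartitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (g in seq_len(k + 1L)) rec(c(assign, g), max(k, g))
  }
  rec(integer(0), 0L)
  out
}

# modularity of a partition of an undirected unweighted edge list
modularityOf <- function(edges, membership) {
  m <- nrow(edges)
  deg <- table(factor(c(edges[, 1], edges[, 2]),
                      levels = seq_along(membership)))
  q <- 0
  for (c in unique(membership)) {
    inC <- which(membership == c)
    ec <- sum(edges[, 1] %in% inC & edges[, 2] %in% inC)
    dc <- sum(deg[inC])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

bruteBestPartition <- function(edges, n) {
  parts <- allPartitions(n)
  qs <- vapply(parts, function(p) modularityOf(edges, p), 0)
  list(membership = parts[[which.max(qs)]], Q = max(qs))
}

# O(n^2) interval overlap: which genes share >= 1 bp with another gene
# on the same scaffold
bruteOverlapped <- function(scaffold, start, end) {
  n <- length(start)
  ov <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || scaffold[i] != scaffold[j]) next
      if (start[i] <= end[j] && start[j] <= end[i]) ov[i] <- TRUE
    }
  }
  ov
}
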