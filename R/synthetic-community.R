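# Synthetic community generator: log-normal compositional abundance
# profiles with a Gaussian copula on the log scale, structural zeros from
# per-OTU occupancy, and multinomial read-depth sampling. Ground truth
# (the planted basis correlations and the latent log-abundance matrix) is
# returned alongside so every downstream estimator can be scored against
# what was actually planted.

#' Community simulation configuration
#'
#' @param n_otus number of OTUs
#' @param n_samples number of samples (default 88, a typical multi-site,
#'   multi-season hot-spring survey size)
#' @param planted_pairs list of \code{c(otu_a, otu_b, basis_correlation)}
#'   triples; correlations in [-1, 1], indices distinct and in range
#' @param mean_log_abundance mean of log basis abundance
#' @param sd_log_abundance sd of log basis abundance (> 0)
#' @param occupancy probability (scalar or per-OTU) in (0, 1] that an OTU
#'   is present in a sample; absences are structural zeros
#' @param read_depth expected total counts per sample (> 0)
#' @param seed master integer seed
#' @return validated config list of class \code{CommunityConfig}
#' @export
communityConfig <- function(n_otus, n_samples = 88, planted_pairs = list(),
                            mean_log_abundance = 0, sd_log_abundance = 1,
                            occupancy = 1, read_depth = 1e5, seed = 1) {
  stopifnot(n_otus >= 2, n_samples >= 2)
  if (sd_log_abundance <= 0) .fail("sd_log_abundance must be > 0")
  if (read_depth <= 0) .fail("read_depth must be > 0")
  .checkProb(occupancy, "occupancy", lo = 0, hi = 1, lo.open = TRUE)
  if (!length(occupancy) %in% c(1L, n_otus))
    .fail("occupancy must be scalar or length n_otus")
  for (p in planted_pairs) {
    if (length(p) != 3) .fail("each planted pair must be (a, b, correlation)")
    a <- p[1]; b <- p[2]; r <- p[3]
    if (a == b || a < 1 || b < 1 || a > n_otus || b > n_otus)
      .fail("planted pair indices must be distinct and within 1..n_otus")
    if (abs(r) > 1) .fail("planted correlation must lie in [-1, 1]")
  }
  structure(list(n_otus = as.integer(n_otus),
                 n_samples = as.integer(n_samples),
                 planted_pairs = planted_pairs,
                 mean_log_abundance = mean_log_abundance,
                 sd_log_abundance = sd_log_abundance,
                 occupancy = rep(occupancy, length.out = n_otus),
                 read_depth = read_depth,
                 seed = as.integer(seed)),
            class = "CommunityConfig")
}

#' Generate a synthetic community depth table with planted correlations
#'
#' Latent log basis abundances are drawn from a multivariate normal whose
#' correlation matrix carries the planted pairwise basis correlations
#' (identity elsewhere). Abundances are exponentiated, zeroed where the
#' per-OTU occupancy draw marks the OTU absent, converted to per-sample
#' relative abundances, and scaled to integer depths by multinomial
#' sampling at \code{read_depth} per sample. The same seed reproduces the
#' table exactly.
#'
#' @param config a \code{\link{communityConfig}}
#' @return list with \code{otu_table} (an \linkS4class{OtuTable} whose
#'   members are the synthetic per-OTU marker ids) and \code{truth} (list:
#'   \code{true_basis_correlations}, \code{planted_partner},
#'   \code{basis_log} latent log-abundance matrix before zeroing,
#'   \code{presence} the occupancy mask)
#' @export
generateCommunity <- function(config) {
  stopifnot(inherits(config, "CommunityConfig"))
  D <- config$n_otus; n <- config$n_samples
  C <- diag(D)
  for (p in config$planted_pairs) {
    C[p[1], p[2]] <- C[p[2], p[1]] <- p[3]
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    .fail(paste("planted correlation matrix is not positive semi-definite",
                "(min eigenvalue %.3g); reduce or re-arrange planted pairs"),
          min(ev))
  set.seed(streamSeed(config$seed, "community"))
  L <- chol(C + diag(1e-12, D))
  Z <- t(L) %*% matrix(rnorm(D * n), D, n)           # D x n, correlated
  logA <- config$mean_log_abundance + config$sd_log_abundance * Z
  present <- matrix(rbinom(D * n, 1, rep(config$occupancy, n)), D, n) == 1
  # a positively associated planted pair emulates a host-dependent
  # symbiont: the pair occupies the same samples (shared habitat), so
  # its presence pattern is shared, not drawn independently
  for (p in config$planted_pairs) {
    if (p[3] > 0) present[p[2], ] <- present[p[1], ]
  }
  basis <- exp(logA) * present
  depth <- matrix(0, D, n)
  for (j in seq_len(n)) {
    cs <- sum(basis[, j])
    if (cs > 0) {
      frac <- basis[, j] / cs
      depth[, j] <- rmultinom(1, size = config$read_depth, prob = frac)
    }
  }
  ids <- sprintf("OTU_%03d", seq_len(D))
  rownames(depth) <- ids
  colnames(depth) <- sprintf("S%03d", seq_len(n))
  rownames(logA) <- rownames(present) <- ids
  colnames(logA) <- colnames(present) <- colnames(depth)
  dimnames(C) <- list(ids, ids)
  markers <- sprintf("marker_%03d", seq_len(D))
  tab <- OtuTable(depth,
                  representative = markers,
                  members = as.list(markers),
                  taxonomy = rep(NA_character_, D))
  partner <- if (length(config$planted_pairs))
    ids[config$planted_pairs[[1]][1:2]] else NULL
  list(otu_table = tab,
       truth = list(true_basis_correlations = C,
                    planted_partner = partner,
                    basis_log = logA,
                    presence = present))
}
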