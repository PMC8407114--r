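# Compositionality-aware basis correlation estimation from count data.
# The estimator works on log-ratio variances t_ij = Var[log(f_i/f_j)]
# and recovers latent per-component ("basis") variances omega_i^2 under a
# sparsity assumption (most pairs uncorrelated), then
# rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 omega_i omega_j).
# Strongly correlated pairs violate the sparsity assumption, so the
# strongest pair is excluded from the sums and the system re-solved, up
# to a fixed number of rounds. Edge significance comes from permutation
# pseudo-p values (per-OTU shuffling of sample labels).

#' Estimate component fractions from a count/depth table
#'
#' Deterministic mode returns pseudocounted proportions per sample.
#' Resampling mode draws \code{n_resamples} Dirichlet vectors per sample
#' with parameters (count + 1) — the posterior under a uniform prior —
#' for averaging the downstream basis estimates over the uncertainty of
#' the fractions.
#'
#' @param depth non-negative OTU-by-sample matrix (or
#'   \linkS4class{OtuTable})
#' @param pseudocount added to every count in deterministic mode
#' @param n_resamples number of Dirichlet draws (resampling mode)
#' @param seed integer seed for the Dirichlet draws
#' @param mode "deterministic" or "dirichlet"
#' @return list of class \code{FractionEstimate}: \code{fractions} (one
#'   matrix, deterministic) or \code{draws} (list of matrices), plus the
#'   parameters used; all columns sum to 1 and entries are > 0
#' @export
estimateFractions <- function(depth, pseudocount = 1, n_resamples = 20,
                              seed = 1,
                              mode = c("deterministic", "dirichlet")) {
  mode <- match.arg(mode)
  if (is(depth, "OtuTable")) depth <- otuDepth(depth)
  depth <- as.matrix(depth)
  if (any(depth < 0)) .fail("estimateFractions: negative depths")
  D <- nrow(depth)
  if (D < 4) .fail(paste("estimateFractions: need >= 4 OTUs for basis",
                         "variance identifiability (have %d)"), D)
  if (ncol(depth) < 3) .fail("estimateFractions: need >= 3 samples")
  if (mode == "deterministic") {
    f <- depth + pseudocount
    f <- sweep(f, 2, colSums(f), "/")
    structure(list(fractions = f, pseudocount = pseudocount,
                   n_resamples = 0L, mode = mode),
              class = "FractionEstimate")
  } else {
    if (n_resamples < 1) .fail("n_resamples must be >= 1")
    set.seed(seed)
    draws <- lapply(seq_len(n_resamples), function(r) {
      g <- matrix(stats::rgamma(length(depth), shape = depth + 1, rate = 1),
                  nrow = D)
      g <- pmax(g, 1e-300)
      sweep(g, 2, colSums(g), "/")
    })
    draws <- lapply(draws, function(d) { dimnames(d) <- dimnames(depth); d })
    structure(list(draws = draws, pseudocount = 1, n_resamples = n_resamples,
                   mode = mode),
              class = "FractionEstimate")
  }
}

# log-ratio variance matrix from one fraction matrix (D x n)
.logRatioVar <- function(f) {
  y <- log(f)
  V <- stats::cov(t(y))
  v <- diag(V)
  t_ij <- outer(v, v, "+") - 2 * V
  diag(t_ij) <- 0
  t_ij
}

# solve for basis variances given t and an exclusion mask: under the
# sparsity approximation t_i = sum_{j in inc(i)} t_ij satisfies
# t_i = d_i w_i + sum_{j in inc(i)} w_j with d_i the number of
# non-excluded partners of i, i.e. M w = t_rowsums with M_ij = 1 for
# included pairs and M_ii = d_i (ones + diag(D - 2) with no exclusions);
# with no exclusions this is equivalent to the closed form
# omega_i^2 = (t_i - W) / (D - 2), W = sum_i t_i / (2 (D - 1)).
.solveBasisVar <- function(t_ij, excluded) {
  D <- nrow(t_ij)
  inc <- !excluded
  diag(inc) <- FALSE
  M <- matrix(1, D, D)
  M[excluded] <- 0
  diag(M) <- rowSums(inc)
  tt <- t_ij
  tt[excluded] <- 0
  ti <- rowSums(tt)
  w <- tryCatch(solve(M, ti), error = function(e) rep(NA_real_, D))
  w
}

.basisFromT <- function(t_ij, exclusion_threshold, max_exclusion_iters,
                        var_floor = 1e-12) {
  D <- nrow(t_ij)
  if (D - 2 <= 0) .fail("basis estimation requires > 2 components")
  excluded <- matrix(FALSE, D, D)
  for (iter in 0:max_exclusion_iters) {
    w <- .solveBasisVar(t_ij, excluded)
    if (anyNA(w)) break
    if (any(w < var_floor)) {
      warning("negative/zero basis variance floored", call. = FALSE)
      w <- pmax(w, var_floor)
    }
    s <- sqrt(w)
    rho <- (outer(w, w, "+") - t_ij) / (2 * outer(s, s))
    rho <- pmin(pmax(rho, -1), 1)
    diag(rho) <- 1
    if (iter == max_exclusion_iters) break
    cand <- abs(rho)
    cand[excluded] <- 0
    diag(cand) <- 0
    m <- max(cand)
    if (m <= exclusion_threshold) break
    idx <- which(cand == m, arr.ind = TRUE)[1, ]
    excluded[idx[1], idx[2]] <- excluded[idx[2], idx[1]] <- TRUE
  }
  list(t = t_ij, omega_sq = w, rho = rho,
       excluded_pairs = which(excluded & upper.tri(excluded), arr.ind = TRUE))
}

#' Basis correlations from estimated fractions
#'
#' Computes the log-ratio variance matrix and solves for basis variances
#' under the sparsity approximation, iteratively excluding the currently
#' strongest pair with |rho| above \code{exclusion_threshold} from the
#' sums and re-solving, up to \code{max_exclusion_iters} rounds. With a
#' Dirichlet-resampled \code{FractionEstimate} the estimates are averaged
#' over the draws. Negative basis variances are floored at 1e-12 with a
#' warning.
#'
#' @param fractions a \code{FractionEstimate} (or a plain fraction matrix)
#' @param exclusion_threshold |rho| above which the strongest pair is
#'   excluded from the sparsity sums
#' @param max_exclusion_iters maximum exclusion rounds
#' @return list of class \code{BasisEstimate}: \code{t} (log-ratio
#'   variance matrix), \code{omega_sq} (basis variances), \code{rho}
#'   (basis correlation matrix, clipped to [-1, 1], unit diagonal),
#'   \code{excluded_pairs}
#' @export
basisCorrelations <- function(fractions, exclusion_threshold = 0.1,
                              max_exclusion_iters = 10) {
  if (is.matrix(fractions))
    fractions <- structure(list(fractions = fractions,
                                mode = "deterministic"),
                           class = "FractionEstimate")
  stopifnot(inherits(fractions, "FractionEstimate"))
  mats <- if (fractions$mode == "deterministic")
    list(fractions$fractions) else fractions$draws
  ests <- lapply(mats, function(f)
    .basisFromT(.logRatioVar(f), exclusion_threshold, max_exclusion_iters))
  if (length(ests) == 1L) {
    out <- ests[[1]]
  } else {
    out <- list(
      t = Reduce(`+`, lapply(ests, `[[`, "t")) / length(ests),
      omega_sq = Reduce(`+`, lapply(ests, `[[`, "omega_sq")) / length(ests),
      rho = Reduce(`+`, lapply(ests, `[[`, "rho")) / length(ests),
      excluded_pairs = ests[[1]]$excluded_pairs
    )
    out$rho <- pmin(pmax(out$rho, -1), 1)
    diag(out$rho) <- 1
  }
  nm <- rownames(mats[[1]])
  if (!is.null(nm)) {
    dimnames(out$rho) <- dimnames(out$t) <- list(nm, nm)
    names(out$omega_sq) <- nm
  }
  class(out) <- "BasisEstimate"
  out
}

#' Convenience: basis correlations straight from a depth table
#'
#' @inheritParams estimateFractions
#' @inheritParams basisCorrelations
#' @return a \code{BasisEstimate}
#' @export
sparccRho <- function(depth, pseudocount = 1, n_resamples = 20, seed = 1,
                      mode = "dirichlet", exclusion_threshold = 0.1,
                      max_exclusion_iters = 10) {
  fr <- estimateFractions(depth, pseudocount = pseudocount,
                          n_resamples = n_resamples, seed = seed,
                          mode = mode)
  basisCorrelations(fr, exclusion_threshold, max_exclusion_iters)
}

#' Permutation pseudo-p values for basis correlations
#'
#' For each permutation round, every OTU's depths are shuffled across
#' samples independently (destroying all inter-OTU association while
#' preserving marginals) and the full basis-correlation matrix is
#' recomputed with the same estimator settings. The two-sided pseudo-p
#' of pair (i, j) is the fraction of permutations whose |rho_null| meets
#' or exceeds |rho_observed|; resolution is 1/n_permutations and p may be
#' exactly 0. With \code{include_identity = TRUE} the unpermuted table is
#' counted as one of the rounds, bounding every p below by
#' 1/n_permutations (sanity mode).
#'
#' @param depth OTU-by-sample depth matrix (or \linkS4class{OtuTable})
#' @param rho_observed observed basis correlation matrix from the same
#'   table
#' @param n_permutations number of permutation rounds (>= 1)
#' @param seed integer seed
#' @param include_identity count the unpermuted table as a round
#' @param ... passed to \code{\link{sparccRho}} for the null recomputes
#'   (defaults: deterministic fractions for speed)
#' @return symmetric matrix of pseudo-p values, NA on the diagonal
#' @export
pseudoP <- function(depth, rho_observed, n_permutations = 100, seed = 1,
                    include_identity = FALSE, ...) {
  if (is(depth, "OtuTable")) depth <- otuDepth(depth)
  depth <- as.matrix(depth)
  if (n_permutations < 1) .fail("n_permutations must be >= 1")
  D <- nrow(depth); n <- ncol(depth)
  dots <- list(...)
  nullRho <- function(d) {
    do.call(sparccRho, c(list(depth = d,
                              mode = dots$mode %||% "deterministic",
                              n_resamples = dots$n_resamples %||% 1,
                              seed = dots$seed %||% 1),
                         dots[setdiff(names(dots),
                                      c("mode", "n_resamples", "seed"))]))$rho
  }
  set.seed(seed)
  counts <- matrix(0, D, D)
  obs <- abs(rho_observed)
  nRounds <- n_permutations
  if (include_identity) {
    counts <- counts + (abs(nullRho(depth)) >= obs)
    nRounds <- n_permutations - 1L
  }
  for (r in seq_len(nRounds)) {
    perm <- depth
    for (i in seq_len(D)) perm[i, ] <- perm[i, sample.int(n)]
    counts <- counts + (abs(nullRho(perm)) >= obs)
  }
  p <- counts / n_permutations
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho_observed)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
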