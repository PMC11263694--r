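# Shared fixtures and independent oracles used across test files.

# Exhaustive-enumeration Viterbi oracle: scores every possible path and
# returns the set of optimal paths together with the maximal log-probability
# (the decoded path must score max_lp and lie in the optimal set; with
# continuous random parameters the optimum is almost surely unique).
viterbi_enum_oracle <- function(obs, pi, A, B) {
  n <- length(obs)
  K <- length(pi)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  lp <- log(pi[paths[, 1]]) + log(B[cbind(paths[, 1], obs[1])])
  if (n > 1) for (t in 2:n) {
    lp <- lp + log(A[cbind(paths[, t - 1], paths[, t])]) +
      log(B[cbind(paths[, t], obs[t])])
  }
  mx <- max(lp)
  best <- paths[lp >= mx - 1e-9, , drop = FALSE]
  storage.mode(best) <- "integer"
  list(max_lp = mx, best = best)
}

# Random row-stochastic matrix.
rand_stoch <- function(nr, nc) {
  m <- matrix(rexp(nr * nc), nr, nc)
  m / rowSums(m)
}

# Random HMM over the 4-symbol alphabet with K states; entries bounded away
# from zero so log-space paths stay finite.
rand_hmm <- function(K, M = 4) {
  list(pi = as.numeric(rand_stoch(1, K)) * 0.9 + 0.1 / K,
       A = rand_stoch(K, K) * 0.9 + 0.1 / K,
       B = rand_stoch(K, M) * 0.9 + 0.1 / M)
}

norm_hmm <- function(h) {
  h$pi <- h$pi / sum(h$pi)
  h$A <- h$A / rowSums(h$A)
  h$B <- h$B / rowSums(h$B)
  h
}

# Random stable VAR coefficient set with a guaranteed directed coupling
# (source column -> target row).  Per-lag dynamics are diagonal with
# clearly detectable magnitudes and the coupling enters only at lag 1, so
# random cross-lag terms can never cancel the planted influence; the
# one-way structure keeps the companion matrix block-triangular and the
# system stable whenever the per-channel AR polynomials are.
rand_stable_var <- function(m = 2, p = 3, sd = NULL, couple = c(2, 1),
                            strength = 0.35, max_radius = 0.9) {
  repeat {
    A <- lapply(seq_len(p), function(k)
      diag(sample(c(-1, 1), m, TRUE) * runif(m, 0.15, 0.35), m))
    A[[1]][couple[1], couple[2]] <- strength
    if (lfpstates:::var_spectral_radius(A) < max_radius) return(A)
  }
}

TABLE_A <- matrix(c(0.98, 0.01, 0.01,
                    0.01, 0.87, 0.12,
                    0.04, 0.06, 0.90), 3, 3, byrow = TRUE)
TABLE_B <- matrix(c(0.98, 0.00, 0.01, 0.01,
                    0.01, 0.21, 0.00, 0.78,
                    0.08, 0.59, 0.29, 0.04), 3, 4, byrow = TRUE,
                  dimnames = list(NULL, c("LoLo", "HiHi", "LoHi", "HiLo")))
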