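# Median-threshold symbolization and the 3-state / 4-symbol discrete HMM:
# Baum-Welch estimation, Viterbi decoding, canonical role labeling, dwell
# times, and overlap with manual behavior labels.

#' Symbol sequence over the 4-letter sensor alphabet
#'
#' @param symbols character vector over `LoLo, HiHi, LoHi, HiLo`.
#' @param step_duration seconds per step.
#' @return object of class `symbol_sequence`.
#' @export
symbol_sequence <- function(symbols, step_duration = 0.5) {
  symbols <- as.character(symbols)
  if (length(symbols) < 1) stop_invalid("symbol sequence must be non-empty")
  bad <- setdiff(unique(symbols), SYMBOLS)
  if (length(bad))
    stop_invalid("unknown symbol(s): ", paste(bad, collapse = ", "),
                 " (alphabet is ", paste(SYMBOLS, collapse = ", "), ")")
  structure(list(symbols = symbols, step_duration = step_duration),
            class = "symbol_sequence")
}

#' @export
length.symbol_sequence <- function(x) length(x$symbols)

#' Median-threshold symbolization of the two sensors
#'
#' Each step is labeled `Hi` on a sensor iff its value strictly exceeds the
#' session median of that sensor (ties map to `Lo`, so constant signals are
#' "inactive").  The first letter is the ACL state, the second the DLC state;
#' `LoHi` therefore means low ACL with high DLC.
#'
#' @param acl,dlc [sensor_series()] of equal length and step.
#' @return [symbol_sequence()].
#' @export
symbolize <- function(acl, dlc) {
  stopifnot(inherits(acl, "sensor_series"), inherits(dlc, "sensor_series"))
  if (length(acl$values) != length(dlc$values))
    stop_invalid("ACL and DLC series differ in length (",
                 length(acl$values), " vs ", length(dlc$values), ")")
  if (abs(acl$dt - dlc$dt) > 1e-9)
    stop_invalid("ACL and DLC series differ in step duration")
  a_hi <- acl$values > median(acl$values)
  d_hi <- dlc$values > median(dlc$values)
  sym <- paste0(ifelse(a_hi, "Hi", "Lo"), ifelse(d_hi, "Hi", "Lo"))
  symbol_sequence(sym, step_duration = acl$dt)
}

rdirichlet_row <- function(k) {
  x <- rgamma(k, shape = 1)
  x / sum(x)
}

#' Fit a discrete-emission HMM by Baum-Welch EM
#'
#' Scaled forward-backward expectation-maximization with random restarts.
#' Each restart draws the initial distribution and the rows of the transition
#' and emission matrices from a flat Dirichlet.  Per-iteration log-likelihood
#' is asserted non-decreasing (within 1e-8); emission zeros are floored at
#' 1e-12 during EM and the final matrices renormalized.  The restart with the
#' highest final log-likelihood is returned, uncanonicalized (see
#' [canonicalize_states()]).
#'
#' @param symbols [symbol_sequence()].
#' @param n_states number of hidden states (default 3).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed.
#' @param tol EM stops when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @param max_iter iteration cap per restart (default 500).
#' @return [hmm_params()] with attributes `loglik`, `n_iter`, `converged`.
#' @export
fit_hmm <- function(symbols, n_states = 3, n_restarts = 10, seed = 1,
                    tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(symbols, "symbol_sequence"))
  obs <- match(symbols$symbols, SYMBOLS) - 1L
  n <- length(obs)
  if (n < n_states)
    stop_invalid("sequence of length ", n, " too short to fit ", n_states,
                 " states")
  M <- length(SYMBOLS)
  floor_p <- 1e-12
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(child_seed(seed, paste0("em_restart_", r)))
    pi <- rdirichlet_row(n_states)
    A <- t(vapply(seq_len(n_states), function(i) rdirichlet_row(n_states),
                  numeric(n_states)))
    B <- t(vapply(seq_len(n_states), function(i) rdirichlet_row(M),
                  numeric(M)))
    ll_prev <- -Inf
    ll <- -Inf
    iter <- 0L
    converged <- FALSE
    repeat {
      iter <- iter + 1L
      fb <- hmm_forward_backward(obs, pi, A, B)
      ll <- fb$loglik
      if (ll < ll_prev - 1e-8)
        stop("EM log-likelihood decreased (", ll_prev, " -> ", ll,
             "); numerical failure")
      if (ll - ll_prev < tol && iter > 1L) { converged <- TRUE; break }
      if (iter >= max_iter) break
      ll_prev <- ll
      pi <- pmax(fb$gamma0, floor_p); pi <- pi / sum(pi)
      A <- pmax(fb$xi_sum, floor_p); A <- A / rowSums(A)
      B <- pmax(fb$gamma_sym, floor_p); B <- B / rowSums(B)
    }
    if (is.null(best) || ll > attr(best, "loglik")) {
      colnames(B) <- SYMBOLS
      best <- hmm_params(pi, A, B)
      attr(best, "loglik") <- ll
      attr(best, "n_iter") <- iter
      attr(best, "converged") <- converged
    }
  }
  attr(best, "step_duration") <- symbols$step_duration
  best
}

#' Log-likelihood of a symbol sequence under HMM parameters
#'
#' @param symbols [symbol_sequence()].
#' @param params [hmm_params()].
#' @return scalar log-likelihood.
#' @export
hmm_loglik <- function(symbols, params) {
  obs <- match(symbols$symbols, SYMBOLS) - 1L
  hmm_forward_backward(obs, params$pi, params$A, params$B)$loglik
}

#' Viterbi decoding of the most probable state path
#'
#' Global maximum-probability path in log space; ties break toward the lower
#' state index.
#'
#' @param symbols [symbol_sequence()].
#' @param params [hmm_params()].
#' @return object of class `state_path`: list with integer `states`,
#'   `log_prob` of the decoded path, and `step_duration`.
#' @export
viterbi <- function(symbols, params) {
  stopifnot(inherits(symbols, "symbol_sequence"),
            inherits(params, "hmm_params"))
  obs <- match(symbols$symbols, SYMBOLS) - 1L
  impossible <- colSums(params$B > 0) == 0
  if (any(impossible[obs + 1L])) {
    t_bad <- which(impossible[obs + 1L])[1]
    stop_invalid("symbol '", symbols$symbols[t_bad], "' at step ", t_bad,
                 " has zero probability under every state")
  }
  res <- hmm_viterbi(obs, log(params$pi), log(params$A), log(params$B))
  structure(list(states = res$path, log_prob = res$log_prob,
                 step_duration = symbols$step_duration),
            class = "state_path")
}

#' Resolve label switching by emission signatures
#'
#' Permutes the states of a fitted 3-state model into canonical order: the
#' state with the largest `LoLo` emission becomes state 1 (`sleep`); among
#' the remaining two, the larger `HiLo` emission becomes state 2 (`dmn`);
#' the last is state 3 (`active`).  The permutation is applied consistently
#' to the initial distribution, transition and emission matrices.  Ties break
#' by state index.
#'
#' @param params fitted [hmm_params()] with 3 states and the 4-symbol
#'   alphabet.
#' @return [hmm_params()] with `roles` set and attribute `permutation`
#'   (`permutation[i]` = old index of new state `i`).
#' @export
canonicalize_states <- function(params) {
  stopifnot(inherits(params, "hmm_params"))
  if (params$n_states != 3 || params$n_symbols != length(SYMBOLS))
    stop_invalid("canonical roles are defined for the 3-state, 4-symbol model")
  B <- params$B
  colnames(B) <- colnames(B) %||% SYMBOLS
  sleep <- which.max(B[, "LoLo"])
  rest <- setdiff(1:3, sleep)
  dmn <- rest[which.max(B[rest, "HiLo"])]
  active <- setdiff(rest, dmn)
  perm <- c(sleep, dmn, active)
  out <- hmm_params(params$pi[perm], params$A[perm, perm, drop = FALSE],
                    B[perm, , drop = FALSE], roles = STATE_ROLES)
  attr(out, "permutation") <- perm
  attr(out, "loglik") <- attr(params, "loglik")
  attr(out, "step_duration") <- attr(params, "step_duration")
  out
}

#' Mean dwell time per state
#'
#' Mean length of uninterrupted runs in each state times the step duration.
#' Runs touching the sequence boundaries count like any other run.
#'
#' @param path `state_path` (or `latent_states`) object.
#' @param step_duration seconds per step; defaults to the path's own.
#' @return named numeric vector, seconds; `NA` for states never visited.
#' @export
dwell_times <- function(path, step_duration = path$step_duration) {
  r <- rle(path$states)
  ks <- sort(unique(path$states))
  out <- vapply(ks, function(k) mean(r$lengths[r$values == k]) * step_duration,
                numeric(1))
  names(out) <- paste0("state", ks)
  out
}

#' Behavior label vocabulary and set mapping
#'
#' The 7 fine-grained labels and their grouping into the three behavioral
#' sets: 1 = sleep posture; 2 = DMN-associated (quiet wakefulness,
#' eating/drinking, grooming, nest box); 3 = locomotion/exploration.
#'
#' @format named integer vector: label -> set.
#' @export
BEHAVIOR_SETS <- c(sleep_posture = 1L, quiet_awake = 2L, eating_drinking = 2L,
                   grooming = 2L, nest_box = 2L, locomotion = 3L,
                   exploration = 3L)

#' Overlap between decoded states and manual behavior sets
#'
#' @param path `state_path` object.
#' @param labels character vector of per-epoch labels from the
#'   [BEHAVIOR_SETS] vocabulary (or already-coded integer sets 1-3).
#' @return list with `overlap` (3 x 3 matrix, entry `(i, j)` = fraction of
#'   steps decoded as state `i` whose manual set is `j`; rows sum to 1) and
#'   `composition` (per-state fraction of each fine-grained label, when
#'   labels were given by name).
#' @export
overlap_matrix <- function(path, labels) {
  if (length(labels) != length(path$states))
    stop_invalid("labels (", length(labels), ") and path (",
                 length(path$states), ") differ in length")
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), names(BEHAVIOR_SETS))
    if (length(bad))
      stop_invalid("unknown label(s): ", paste(bad, collapse = ", "))
    sets <- BEHAVIOR_SETS[labels]
    comp <- table(factor(path$states, levels = 1:3),
                  factor(labels, levels = names(BEHAVIOR_SETS)))
    comp <- prop.table(comp + 0, margin = 1)
  } else {
    sets <- as.integer(labels)
    if (any(!sets %in% 1:3)) stop_invalid("integer sets must be in 1..3")
    comp <- NULL
  }
  tab <- table(factor(path$states, levels = 1:3), factor(sets, levels = 1:3))
  ov <- prop.table(tab + 0, margin = 1)
  ov[is.nan(ov)] <- 0
  list(overlap = unclass(ov), composition = if (is.null(comp)) NULL
       else unclass(comp))
}

#' Fraction of time spent in each state
#'
#' @param path `state_path` or `latent_states` object.
#' @return named numeric vector over states 1..3.
#' @export
time_budget <- function(path) {
  tab <- table(factor(path$states, levels = 1:3))
  out <- as.numeric(tab) / length(path$states)
  names(out) <- paste0("state", 1:3)
  out
}
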