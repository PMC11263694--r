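# Symbolization, Baum-Welch, Viterbi, canonical labeling, dwell times and
# manual-label overlap.

test_that("median symbolization follows the hand-checked rule", {
  acl <- sensor_series(c(1, 3, 2, 4), dt = 0.5)
  dlc <- sensor_series(c(5, 1, 6, 2), dt = 0.5)
  expect_identical(symbolize(acl, dlc)$symbols,
                   c("LoHi", "HiLo", "LoHi", "HiLo"))

  const <- sensor_series(rep(2, 6), dt = 0.5)
  expect_true(all(symbolize(const, const)$symbols == "LoLo"))  # ties -> Lo

  # swapping the sensors maps HiLo <-> LoHi and fixes HiHi / LoLo
  set.seed(3)
  a <- sensor_series(rexp(50), dt = 0.5)
  b <- sensor_series(rexp(50), dt = 0.5)
  s1 <- symbolize(a, b)$symbols
  s2 <- symbolize(b, a)$symbols
  map <- c(LoLo = "LoLo", HiHi = "HiHi", HiLo = "LoHi", LoHi = "HiLo")
  expect_identical(unname(map[s1]), s2)

  expect_error(symbolize(a, sensor_series(rexp(10), dt = 0.5)), "length")
})

test_that("EM handles degenerate streams and matches a brute-force optimum", {
  # constant stream: some state owns that symbol almost surely
  sym <- symbol_sequence(rep("HiLo", 200))
  fit <- fit_hmm(sym, n_states = 3, n_restarts = 2, seed = 1)
  expect_gte(max(fit$B[, "HiLo"]), 0.99)

  # strict 2-symbol alternation, 2 states: the deterministic alternating
  # model is the global optimum; compare per-step log-likelihood
  n <- 400
  sym2 <- symbol_sequence(rep(c("LoLo", "HiHi"), n / 2))
  fit2 <- fit_hmm(sym2, n_states = 2, n_restarts = 5, seed = 2)
  det <- hmm_params(c(1, 0),
                    matrix(c(0, 1, 1, 0), 2, 2),
                    rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  ll_det <- hmm_loglik(sym2, det)
  expect_gte(attr(fit2, "loglik") / n, ll_det / n - 1e-3)
  expect_lte(abs(attr(fit2, "loglik") - ll_det) / n, 1e-3)

  expect_error(fit_hmm(symbol_sequence(c("LoLo", "HiHi"))), "too short")
})

test_that("EM recovers generator parameters (scaled-down recovery check)", {
  # scaled from the n=1e5/10-restart acceptance run: n=2e4, 5 restarts
  # (3 restarts can land every start in one local optimum), tolerance
  # widened to 0.03 accordingly
  p <- default_hmm_params()
  for (seed in 1:2) {
    st <- simulate_state_sequence(p, 2e4, seed = seed)
    sym <- simulate_symbols(st, p$B, seed = seed)
    fit <- canonicalize_states(fit_hmm(sym, n_restarts = 5, seed = seed))
    expect_lt(max(abs(fit$A - p$A)), 0.03)
    expect_lt(max(abs(fit$B - p$B)), 0.03)
  }
})

test_that("Viterbi equals the exhaustive-enumeration oracle", {
  syms <- c("LoLo", "HiHi", "LoHi", "HiLo")
  set.seed(4)
  for (i in 1:60) {
    K <- sample(2:3, 1)
    n <- sample(2:8, 1)
    h <- rand_hmm(K)
    obs <- sample(1:4, n, replace = TRUE)
    par <- hmm_params(h$pi / sum(h$pi), h$A / rowSums(h$A),
                      h$B / rowSums(h$B))
    got <- viterbi(symbol_sequence(syms[obs]), par)
    orc <- viterbi_enum_oracle(obs, par$pi, par$A, par$B)
    expect_equal(got$log_prob, orc$max_lp, tolerance = 1e-9)
    expect_true(any(apply(orc$best, 1, function(r) all(r == got$states))))
  }
})

test_that("Viterbi honors deterministic emissions and tie-breaks", {
  syms <- c("LoLo", "HiHi", "LoHi", "HiLo")
  det <- hmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3),
                    rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0)))
  obs <- c(1, 3, 2, 2, 1)
  got <- viterbi(symbol_sequence(syms[obs]), det)
  expect_identical(got$states, c(1L, 3L, 2L, 2L, 1L))

  unif <- hmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3), matrix(0.25, 3, 4))
  expect_true(all(viterbi(symbol_sequence(syms[c(2, 4, 1)]), unif)$states == 1L))

  dead <- hmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3),
                     rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 0.5, 0.5, 0)))
  expect_error(viterbi(symbol_sequence(c("LoLo", "HiLo")), dead), "step 2")
})

test_that("canonicalization restores the printed ordering from any permutation", {
  p <- hmm_params(c(0.6, 0.15, 0.25), TABLE_A, TABLE_B)
  for (perm in list(c(2, 3, 1), c(3, 1, 2), c(3, 2, 1), 1:3)) {
    scrambled <- hmm_params(p$pi[perm], p$A[perm, perm], p$B[perm, ])
    fixed <- canonicalize_states(scrambled)
    expect_equal(fixed$A, p$A, ignore_attr = TRUE)
    expect_equal(fixed$B, p$B, ignore_attr = TRUE)
    expect_identical(fixed$roles, c("sleep", "dmn", "active"))
  }
  # all rows equal: identity permutation by tie-break
  flat <- hmm_params(rep(1 / 3, 3), matrix(1 / 3, 3, 3), matrix(0.25, 3, 4))
  expect_identical(attr(canonicalize_states(flat), "permutation"), 1:3)
})

test_that("dwell times average run lengths", {
  path <- structure(list(states = c(1L, 1L, 1L, 2L, 2L, 1L),
                         step_duration = 1), class = "state_path")
  dw <- dwell_times(path)
  expect_equal(unname(dw["state1"]), 2)
  expect_equal(unname(dw["state2"]), 2)

  const <- structure(list(states = rep(3L, 7), step_duration = 0.5),
                     class = "state_path")
  expect_equal(unname(dwell_times(const)["state3"]), 3.5)

  # geometric-chain property: self-transition p -> mean dwell ~ step/(1-p)
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  p2 <- hmm_params(c(0.5, 0.5), A, rand_stoch(2, 4))
  st <- simulate_state_sequence(p2, 3e4, seed = 15, step_duration = 1)
  dw <- dwell_times(st)
  expect_equal(unname(dw["state1"]), 10, tolerance = 0.1)
})

test_that("overlap matrices count decoded-state / manual-set agreement", {
  path <- structure(list(states = c(1L, 1L, 2L), step_duration = 0.5),
                    class = "state_path")
  ov <- overlap_matrix(path, c(1L, 2L, 2L))
  expect_equal(ov$overlap[1, ], c(0.5, 0.5, 0), ignore_attr = TRUE)
  expect_equal(ov$overlap[2, ], c(0, 1, 0), ignore_attr = TRUE)

  # labels by name, identical to the mapped path -> identity overlap
  labs <- c("sleep_posture", "grooming", "locomotion")[c(1, 1, 2, 3, 3)]
  path2 <- structure(list(states = c(1L, 1L, 2L, 3L, 3L),
                          step_duration = 0.5), class = "state_path")
  ov2 <- overlap_matrix(path2, labs)
  expect_equal(diag(ov2$overlap), rep(1, 3), ignore_attr = TRUE)
  expect_equal(ov2$composition["2", "grooming"], 1, ignore_attr = TRUE)

  # labels independent of the path: rows approach the set frequencies
  set.seed(6)
  pathr <- structure(list(states = sample(1:3, 6000, TRUE),
                          step_duration = 0.5), class = "state_path")
  sets <- sample(1:3, 6000, TRUE, prob = c(0.5, 0.3, 0.2))
  ovr <- overlap_matrix(pathr, sets)
  for (i in 1:3)
    expect_equal(unname(ovr$overlap[i, ]), c(0.5, 0.3, 0.2),
                 tolerance = 0.12)
  expect_error(overlap_matrix(pathr, sets[-1]), "length")
})
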