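# VAR estimation, order selection, time- and frequency-domain Granger
# causality, and significance handling.

test_that("VAR least squares recovers known coefficients", {
  set.seed(10)
  x <- as.numeric(arima.sim(list(ar = 0.5), 1e4))
  vm <- fit_var(matrix(x, ncol = 1), 1)
  expect_equal(vm$coeffs[[1]][1, 1], 0.5, tolerance = 0.04)

  Xi <- matrix(rnorm(2e4), ncol = 2)
  vmi <- fit_var(Xi, 1)
  expect_lt(max(abs(vmi$coeffs[[1]][row(vmi$coeffs[[1]]) !=
                                      col(vmi$coeffs[[1]])])), 0.05)
  expect_error(fit_var(Xi, 0), ">= 1")
})

test_that("segment-aware regression never straddles boundaries", {
  set.seed(11)
  segs <- list(matrix(rnorm(200), ncol = 2), matrix(rnorm(300), ncol = 2))
  vm <- fit_var(segs, 3)
  expect_identical(vm$n_obs, (100L - 3L) + (150L - 3L))
  # a segment shorter than the order is skipped, not an error
  vm2 <- fit_var(c(segs, list(matrix(rnorm(4), ncol = 2))), 3)
  expect_identical(vm2$n_obs, vm$n_obs)
})

test_that("AIC order selection finds the generating order", {
  fs <- 400
  expect_length(select_order(matrix(rnorm(4000), ncol = 2), fs)$aic, 8)

  hits <- 0
  for (s in 1:5) {
    set.seed(20 + s)
    A <- rand_stable_var(m = 2, p = 3)
    X <- simulate_var(A, diag(2), 1e4, seed = 20 + s)
    if (select_order(X, fs)$p == 3) hits <- hits + 1
  }
  expect_gte(hits, 3)

  wn_hits <- 0
  for (s in 1:5) {
    set.seed(30 + s)
    if (select_order(matrix(rnorm(2e4), ncol = 2), fs)$p == 1)
      wn_hits <- wn_hits + 1
  }
  expect_gte(wn_hits, 3)
})

test_that("time-domain GC matches a two-model OLS oracle and is directional", {
  set.seed(12)
  n <- 1e4
  x <- rnorm(n)
  y <- c(0, 0.9 * x[-n]) + rnorm(n)
  X <- cbind(x = x, y = y)
  p <- 2
  fwd <- gc_time_conditional(X, "x", "y", p = p)
  rev <- gc_time_conditional(X, "y", "x", p = p)

  # independent oracle: two explicit demeaned OLS fits
  rows <- (p + 1):n
  dm <- function(m) sweep(m, 2, colMeans(m))
  Zf <- dm(cbind(y[rows - 1], y[rows - 2], x[rows - 1], x[rows - 2]))
  Zr <- dm(cbind(y[rows - 1], y[rows - 2]))
  yc <- y[rows] - mean(y[rows])
  rss <- function(Y, Z) {
    b <- solve(crossprod(Z), crossprod(Z, Y))
    sum((Y - Z %*% b)^2)
  }
  expect_equal(fwd$F_time, log(rss(yc, Zr) / rss(yc, Zf)), tolerance = 1e-6)
  expect_equal(fwd$F_time, log(1 + 0.81), tolerance = 0.05)
  expect_lt(rev$F_time, 0.01)

  # fully independent channels: all F < 0.01
  Xn <- matrix(rnorm(3e4), ncol = 3)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_lt(gc_time_conditional(Xn, i, j, setdiff(1:3, c(i, j)),
                                  p = 2)$F_time, 0.01)
  }

  # an unrelated conditioning channel barely moves F
  z <- rnorm(n)
  X3 <- cbind(X, z = z)
  fwd_c <- gc_time_conditional(X3, "x", "y", "z", p = p)
  expect_lt(abs(fwd_c$F_time - fwd$F_time), 0.02)
  expect_error(gc_time_conditional(X, "x", "x", p = 1), "differ")
  expect_error(gc_time_conditional(X3, "x", "y", "x", p = 1), "exclude")
})

test_that("spectral GC is band-specific, non-negative, and integrates to F", {
  fs <- 400
  # one-way coupling routed through a sharp 50 Hz resonator in the source:
  # the received influence is concentrated in the gamma band
  r <- 0.95; w0 <- 2 * pi * 50 / fs
  A1 <- rbind(c(2 * r * cos(w0), 0), c(0.3, 0))
  A2 <- rbind(c(-r^2, 0), c(0, 0))
  X <- simulate_var(list(A1, A2), diag(2), 1e4, seed = 40)
  g <- gc_spectral(X, 1, 2, integer(0), p = 3, fs = fs)
  expect_true(all(g$spectrum > -1e-9))
  expect_gt(g$band_means[["gamma"]] / max(g$band_means[["delta"]], 1e-12), 5)

  # Geweke integral identity on planted-coupling stable VAR(3) systems
  for (s in 1:3) {
    set.seed(50 + s)
    A <- rand_stable_var(m = 2, p = 3)
    Xs <- simulate_var(A, diag(2), 1e4, seed = 50 + s)
    gs <- gc_spectral(Xs, 1, 2, integer(0), p = 3, fs = fs, p_reduced = 12)
    expect_lt(abs(mean(gs$spectrum) - gs$F_time) / gs$F_time, 0.05)
  }

  # null coupling: band means ~ 0
  Xn <- matrix(rnorm(2e4), ncol = 2)
  gn <- gc_spectral(Xn, 1, 2, integer(0), p = 2, fs = fs)
  expect_true(all(gn$band_means < 0.01))
})

test_that("GC is invariant to per-channel rescaling", {
  set.seed(13)
  A <- rand_stable_var(m = 3, p = 2, couple = c(2, 1))
  X <- simulate_var(A, diag(3), 5e3, seed = 13)
  g1 <- gc_spectral(X, 1, 2, 3, p = 2, fs = 400)
  Xs <- X %*% diag(c(100, 0.01, 7))
  g2 <- gc_spectral(Xs, 1, 2, 3, p = 2, fs = 400)
  expect_equal(g1$F_time, g2$F_time, tolerance = 1e-6)
  expect_equal(g1$spectrum, g2$spectrum, tolerance = 1e-6)
})

test_that("F-tests and BH adjustment behave", {
  # ties in p-values give equal q-values
  set.seed(14)
  Xn <- matrix(rnorm(4e3 * 4), ncol = 4)
  res <- list()
  for (i in 1:3) {
    r <- gc_time_conditional(Xn, i, 4, setdiff(1:3, i), p = 2)
    res[[i]] <- r
  }
  fake <- res
  for (i in 1:3) { fake[[i]]$rss_full <- 1; fake[[i]]$rss_reduced <- 1.01 }
  q <- gc_significance(fake)$q_value
  expect_true(all(abs(q - q[1]) < 1e-12))

  # one strong true coupling among 12 directions is detected
  det <- 0
  for (s in 1:5) {
    set.seed(60 + s)
    n <- 4000
    E <- matrix(rnorm(n * 4), ncol = 4)
    X <- E
    X[-1, 2] <- X[-1, 2] + 0.3 * X[-n, 1]        # 1 -> 2 only
    res <- list()
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      res[[length(res) + 1]] <-
        gc_time_conditional(X, i, j, setdiff(1:4, c(i, j)), p = 2)
    }
    tab <- gc_significance(res, Q = 0.05)
    hit <- tab$significant[tab$source == "ch1" & tab$target == "ch2"]
    if (hit && sum(tab$significant) <= 3) det <- det + 1
  }
  expect_gte(det, 5)
})

test_that("state segmentation splits contiguous runs", {
  lfp <- matrix(seq_len(20), ncol = 2)
  sps <- c(1, 1, 2, 2, 2, 1, 1, 2, 1, 1)
  segs <- state_segments(lfp, sps, 2, min_len = 2)
  expect_length(segs, 1)                  # the lone state-2 sample is dropped
  expect_identical(nrow(segs[[1]]), 3L)
  segs1 <- state_segments(lfp, sps, 1, min_len = 2)
  expect_identical(vapply(segs1, nrow, integer(1)), c(2L, 2L, 2L))
})
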