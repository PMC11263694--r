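# Ground-truth generator: latent chain, symbol emissions, sensor streams,
# LFP synthesis, and the on-disk formats.

test_that("state sequences follow the transition structure", {
  # absorbing chain: identity transitions pin the chain to its initial state
  pid <- hmm_params(c(0, 1, 0), diag(3), rand_stoch(3, 4))
  st <- simulate_state_sequence(pid, 50, seed = 1)
  expect_true(all(st$states == 2))

  # printed example-session matrix: empirical 1->1 frequency ~ 0.98
  p <- default_hmm_params()
  st <- simulate_state_sequence(p, 1e5, seed = 7)
  tr <- table(head(st$states, -1), tail(st$states, -1))
  expect_equal(tr[1, 1] / sum(tr[1, ]), 0.98, tolerance = 0.005 / 0.98)

  # uniform chain: occupancy ~ 1/3 each
  pu <- hmm_params(rep(1, 3) / 3, matrix(1 / 3, 3, 3), p$B)
  stu <- simulate_state_sequence(pu, 3e4, seed = 2)
  occ <- as.numeric(table(factor(stu$states, 1:3))) / 3e4
  expect_true(all(abs(occ - 1 / 3) < 0.02))

  # reproducibility and validation
  expect_identical(simulate_state_sequence(p, 100, seed = 5)$states,
                   simulate_state_sequence(p, 100, seed = 5)$states)
  expect_error(hmm_params(c(1, 0, 0), matrix(0.5, 3, 3), p$B), "sum to 1")
})

test_that("symbol emissions follow the emission rows", {
  p <- default_hmm_params()
  # deterministic emissions relabel the states
  Bdet <- diag(3)[, c(1, 2, 3)]
  Bdet <- cbind(Bdet, 0)  # 3 x 4, state k -> symbol k
  st <- simulate_state_sequence(p, 500, seed = 3)
  sym <- simulate_symbols(st, Bdet, seed = 3)
  expect_identical(match(sym$symbols, c("LoLo", "HiHi", "LoHi", "HiLo")),
                   st$states)

  # printed state-2 row: Hi/Lo frequency ~ 0.78
  st2 <- structure(list(states = rep(2L, 1e4), step_duration = 0.5),
                   class = "latent_states")
  sym2 <- simulate_symbols(st2, TABLE_B, seed = 4)
  expect_equal(mean(sym2$symbols == "HiLo"), 0.78, tolerance = 0.01 / 0.78)

  # uniform emissions: each symbol ~ 1/4
  symu <- simulate_symbols(
    structure(list(states = sample(1:3, 4e4, TRUE), step_duration = 0.5),
              class = "latent_states"),
    matrix(0.25, 3, 4), seed = 5)
  frq <- as.numeric(table(factor(symu$symbols,
                                 c("LoLo", "HiHi", "LoHi", "HiLo")))) / 4e4
  expect_true(all(abs(frq - 0.25) < 0.01))

  expect_error(simulate_symbols(st, matrix(0.3, 3, 4), seed = 1), "sum to 1")
})

test_that("sensor streams respect the per-state profile", {
  # zero dispersion: values exactly the per-state log-medians
  p <- default_hmm_params()
  st <- simulate_state_sequence(p, 200, seed = 6)
  prof0 <- sensor_profile(acl_meanlog = c(-1, 0, 1), acl_sdlog = rep(0, 3),
                          dlc_meanlog = c(0, 1, 2), dlc_sdlog = rep(0, 3))
  sens0 <- simulate_sensors(st, prof0, seed = 6)
  expect_equal(sens0$acl$values, exp(c(-1, 0, 1))[st$states])
  expect_equal(sens0$dlc$values, exp(c(0, 1, 2))[st$states])

  # separated profile with state 1 at half occupancy: both session medians
  # fall in the gap above state 1's clusters -> almost pure LoLo
  ph <- hmm_params(c(0.5, 0.25, 0.25),
                   matrix(c(0.5, 0.25, 0.25), 3, 3, byrow = TRUE), p$B)
  stu <- simulate_state_sequence(ph, 2e4, seed = 8)
  prof <- sensor_profile(acl_meanlog = c(-3, 2, 2), acl_sdlog = rep(0.3, 3),
                         dlc_meanlog = c(-3, 2, 2), dlc_sdlog = rep(0.3, 3))
  sens <- simulate_sensors(stu, prof, seed = 8)
  sym <- symbolize(sens$acl, sens$dlc)
  expect_gt(mean(sym$symbols[stu$states == 1] == "LoLo"), 0.95)

  # all states share one distribution: medians split 50/50 independently
  prof_same <- sensor_profile(acl_meanlog = rep(0, 3), acl_sdlog = rep(1, 3),
                              dlc_meanlog = rep(0, 3), dlc_sdlog = rep(1, 3))
  sens_s <- simulate_sensors(stu, prof_same, seed = 9)
  sym_s <- symbolize(sens_s$acl, sens_s$dlc)
  frq <- as.numeric(table(factor(sym_s$symbols,
                                 c("LoLo", "HiHi", "LoHi", "HiLo")))) / 2e4
  expect_true(all(abs(frq - 0.25) < 0.02))
  expect_error(sensor_profile(0, -1, 0, 1), ">= 0")
})

test_that("symbolization of well-separated sensors reproduces emissions", {
  # a median-split puts the threshold in a between-cluster gap only where
  # the cumulative occupancy hits 0.5 at a cluster boundary; with state 1
  # at half occupancy and far below both medians, every state maps
  # deterministically to one symbol (1 -> LoLo, 2 and 3 -> HiHi) and the
  # empirical emissions must reproduce that matrix
  ph <- hmm_params(c(0.5, 0.25, 0.25),
                   matrix(c(0.5, 0.25, 0.25), 3, 3, byrow = TRUE),
                   default_hmm_params()$B)
  stu <- simulate_state_sequence(ph, 2e4, seed = 12)
  prof <- sensor_profile(acl_meanlog = c(-3, 2, 2), acl_sdlog = rep(0.3, 3),
                         dlc_meanlog = c(-3, 2, 2), dlc_sdlog = rep(0.3, 3))
  sens <- simulate_sensors(stu, prof, seed = 12)
  sym <- symbolize(sens$acl, sens$dlc)
  B_emp <- prop.table(table(factor(stu$states, 1:3),
                            factor(sym$symbols,
                                   c("LoLo", "HiHi", "LoHi", "HiLo"))), 1)
  B_target <- matrix(0, 3, 4)      # 1 -> LoLo, 2 -> HiHi, 3 -> HiHi
  B_target[1, 1] <- 1; B_target[2, 2] <- 1; B_target[3, 2] <- 1
  expect_lt(max(abs(B_emp - B_target)), 0.03)
})

test_that("LFP synthesis is finite, reproducible, and band-structured", {
  p <- default_hmm_params()
  st <- simulate_state_sequence(p, 240, seed = 10)
  lfp <- simulate_lfp(st, fs = 400, seed = 10)
  expect_true(all(is.finite(lfp)))
  expect_identical(dim(lfp), c(240L * 200L, 4L))
  expect_lt(max(abs(colMeans(lfp))), 0.05)     # near zero-mean
  expect_identical(lfp, simulate_lfp(st, fs = 400, seed = 10))

  # per-state gamma power orders as the profile's per-state gamma amplitudes
  # (weak VAR floor so the state-dependent carrier dominates every channel)
  prof <- lfp_profile(delta_amp = c(2, 0.5, 0.3), gamma_amp = c(0.05, 0.3, 0.15),
                      high_gamma_amp = c(0.03, 0.15, 0.08),
                      pac_strength = c(0.1, 0.8, 0.4),
                      pac_angle = c(-3 * pi / 4, -pi / 4, pi / 4, 0),
                      noise_cov = diag(0.03^2, 4))
  st2 <- simulate_state_sequence(p, 600, seed = 11)
  lfp2 <- simulate_lfp(st2, prof, fs = 400, seed = 11)
  ep <- epoch_signal(lfp2, 400)
  gb <- band_power_by_state(band_power(ep, c(40, 60)), st2$states)
  for (ch in 1:4) expect_true(all(diff(gb[c(1, 3, 2), ch]) > 0))
  db <- band_power_by_state(band_power(ep, c(0.5, 4)), st2$states)
  for (ch in 1:4) expect_true(all(diff(db[c(3, 2, 1), ch]) > 0))

  expect_error(lfp_profile(delta_amp = 1:3 * 0.1, gamma_amp = 1:3 * 0.1,
                           high_gamma_amp = 1:3 * 0.1,
                           pac_strength = rep(0, 3), pac_angle = rep(0, 4),
                           var_coefficients = list(diag(1.1, 4))),
               "unstable")
  expect_error(simulate_lfp(st, fs = 200), "300 Hz")
})

test_that("uncoupled LFP shows no phase-amplitude coupling", {
  prof <- lfp_profile(delta_amp = rep(1, 3), gamma_amp = rep(0.3, 3),
                      high_gamma_amp = rep(0.05, 3),
                      pac_strength = rep(0, 3), pac_angle = rep(0, 4))
  st <- simulate_state_sequence(default_hmm_params(), 120, seed = 13)  # 60 s
  lfp <- simulate_lfp(st, prof, fs = 400, seed = 13)
  pa <- analytic_phase_amplitude(bandpass(lfp[, 2], c(0.5, 4), 400),
                                 bandpass(lfp[, 2], c(40, 60), 400))
  v <- cfc_vector(pa$phase, pa$amplitude)
  expect_lt(v$strength, 0.05)
})

test_that("simulation round-trips through the on-disk formats", {
  p <- default_hmm_params()
  st <- simulate_state_sequence(p, 20, seed = 14)
  sens <- simulate_sensors(st, seed = 14)
  lfp <- simulate_lfp(st, fs = 400, seed = 14)
  dir <- withr::local_tempdir()
  write_simulation(dir, st, sens, lfp)
  back <- read_lfp_bin(file.path(dir, "lfp.f32"))
  expect_equal(unname(back[, ]), unname(lfp[, ]), tolerance = 1e-6)
  expect_equal(attr(back, "fs"), attr(lfp, "fs"))
  expect_identical(attr(back, "channels"), attr(lfp, "channels"))
  csv <- read.csv(file.path(dir, "sensors.csv"))
  expect_equal(csv$acl, sens$acl$values)
  expect_identical(csv$true_state, st$states)
})
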