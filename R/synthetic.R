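# Ground-truth generator: latent 3-state behavioral chain, symbol emissions,
# log-normal movement-sensor streams, and multichannel LFPs carrying
# state-dependent band content, planted VAR coupling and planted delta-phase
# -> gamma-amplitude coupling.  Everything is seeded through child_seed() so
# individual streams are independently reproducible.

#' Construct and validate HMM parameters
#'
#' @param pi initial state distribution (length `n_states`).
#' @param A `n_states x n_states` transition matrix, rows sum to 1.
#' @param B `n_states x 4` emission matrix over the symbol alphabet
#'   `LoLo, HiHi, LoHi, HiLo`; rows sum to 1.
#' @param roles optional character vector mapping states to behavioral roles
#'   (`"sleep"`, `"dmn"`, `"active"`); filled by [canonicalize_states()].
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(pi, A, B, roles = NULL) {
  pi <- as.numeric(pi)
  A <- as.matrix(A)
  B <- as.matrix(B)
  K <- length(pi)
  if (!all(dim(A) == c(K, K)))
    stop_invalid("transition matrix must be ", K, "x", K)
  if (nrow(B) != K)
    stop_invalid("emission matrix must have one row per state")
  if (any(pi < 0) || any(A < 0) || any(B < 0))
    stop_invalid("probabilities must be non-negative")
  if (abs(sum(pi) - 1) > 1e-9)
    stop_invalid("initial distribution must sum to 1")
  if (any(abs(rowSums(A) - 1) > 1e-9))
    stop_invalid("transition matrix rows must sum to 1")
  if (any(abs(rowSums(B) - 1) > 1e-9))
    stop_invalid("emission matrix rows must sum to 1")
  if (ncol(B) == length(SYMBOLS) && is.null(colnames(B))) colnames(B) <- SYMBOLS
  structure(list(pi = pi, A = A, B = B, roles = roles,
                 n_states = K, n_symbols = ncol(B)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("HMM with", x$n_states, "states and", x$n_symbols, "symbols\n")
  cat("initial:", round(x$pi, 3), "\n")
  cat("transitions:\n"); print(round(x$A, 3))
  cat("emissions:\n"); print(round(x$B, 3))
  if (!is.null(x$roles)) cat("roles:", x$roles, "\n")
  invisible(x)
}

#' Reference HMM parameters for a typical home-cage session
#'
#' A very sticky sleep state emitting almost only `LoLo`, a DMN-behavior state
#' dominated by `HiLo` (head movement without locomotion), and an active state
#' mixing `HiHi` and `LoHi`.  These are the generator defaults used throughout
#' the tests.
#'
#' @param step_duration symbol step in seconds (attached as attribute).
#' @return `hmm_params` object with canonical roles.
#' @export
default_hmm_params <- function(step_duration = 0.5) {
  A <- matrix(c(0.98, 0.01, 0.01,
                0.01, 0.87, 0.12,
                0.04, 0.06, 0.90), 3, 3, byrow = TRUE)
  B <- matrix(c(0.98, 0.00, 0.01, 0.01,
                0.01, 0.21, 0.00, 0.78,
                0.08, 0.59, 0.29, 0.04), 3, 4, byrow = TRUE,
              dimnames = list(NULL, SYMBOLS))
  p <- hmm_params(pi = c(0.60, 0.15, 0.25), A = A, B = B, roles = STATE_ROLES)
  attr(p, "step_duration") <- step_duration
  p
}

#' Simulate the latent behavioral state sequence
#'
#' Samples a Markov chain from the initial distribution and transition matrix.
#'
#' @param params `hmm_params` object (emissions unused here).
#' @param n_steps number of steps (>= 1).
#' @param seed integer seed.
#' @param step_duration seconds per step.
#' @return object of class `latent_states`: list with integer `states` in
#'   `1..n_states` and `step_duration`.
#' @export
simulate_state_sequence <- function(params, n_steps, seed = 1,
                                    step_duration = attr(params, "step_duration") %||% 0.5) {
  stopifnot(inherits(params, "hmm_params"))
  if (n_steps < 1) stop_invalid("n_steps must be >= 1")
  set.seed(child_seed(seed, "states"))
  K <- params$n_states
  u <- runif(n_steps)
  cumA <- t(apply(params$A, 1, cumsum))
  states <- integer(n_steps)
  states[1] <- findInterval(u[1], cumsum(params$pi)) + 1L
  states[1] <- min(states[1], K)
  for (t in seq_len(n_steps - 1L)) {
    states[t + 1L] <- min(findInterval(u[t + 1L], cumA[states[t], ]) + 1L, K)
  }
  structure(list(states = states, step_duration = step_duration),
            class = "latent_states")
}

#' Simulate output symbols from a latent state sequence
#'
#' @param states `latent_states` object.
#' @param emission `n_states x 4` row-stochastic matrix (columns ordered
#'   `LoLo, HiHi, LoHi, HiLo`).
#' @param seed integer seed.
#' @return [symbol_sequence()] object.
#' @export
simulate_symbols <- function(states, emission, seed = 1) {
  stopifnot(inherits(states, "latent_states"))
  emission <- as.matrix(emission)
  if (any(emission < 0) || any(abs(rowSums(emission) - 1) > 1e-9))
    stop_invalid("emission rows must be non-negative and sum to 1")
  set.seed(child_seed(seed, "symbols"))
  cumB <- t(apply(emission, 1, cumsum))
  u <- runif(length(states$states))
  idx <- vapply(seq_along(u), function(t)
    min(findInterval(u[t], cumB[states$states[t], ]) + 1L, ncol(emission)),
    integer(1))
  symbol_sequence(SYMBOLS[idx], step_duration = states$step_duration)
}

#' Per-state sensor distributions (log-normal)
#'
#' Movement signals are positive and right-skewed; each behavioral state draws
#' its ACL (accelerometer magnitude) and DLC (nose speed) values from a state
#' specific log-normal.  `*_meanlog` is the log-median; `*_sdlog` the
#' log-scale dispersion (must be >= 0; 0 gives the degenerate point mass at
#' `exp(meanlog)`).
#'
#' @param acl_meanlog,acl_sdlog,dlc_meanlog,dlc_sdlog numeric vectors, one
#'   entry per state.
#' @return object of class `sensor_profile`.
#' @export
sensor_profile <- function(acl_meanlog, acl_sdlog, dlc_meanlog, dlc_sdlog) {
  K <- length(acl_meanlog)
  if (length(acl_sdlog) != K || length(dlc_meanlog) != K ||
      length(dlc_sdlog) != K)
    stop_invalid("all profile vectors must have one entry per state")
  if (any(acl_sdlog < 0) || any(dlc_sdlog < 0))
    stop_invalid("dispersions must be >= 0")
  structure(list(acl_meanlog = acl_meanlog, acl_sdlog = acl_sdlog,
                 dlc_meanlog = dlc_meanlog, dlc_sdlog = dlc_sdlog,
                 n_states = K),
            class = "sensor_profile")
}

#' Default sensor profile
#'
#' Sleep: both sensors at a low noise floor.  DMN behaviors: high head
#' vibration (ACL) but nose speed still near the floor.  Active: both high.
#' Because sleep typically occupies over half the session, the session median
#' of each sensor falls inside the pooled low cluster, reproducing the
#' characteristic `HiLo` signature of the DMN state after median
#' symbolization.
#'
#' @return `sensor_profile` object.
#' @export
default_sensor_profile <- function() {
  sensor_profile(acl_meanlog = c(-2.0, 1.0, 1.2), acl_sdlog = c(0.4, 0.5, 0.5),
                 dlc_meanlog = c(-2.0, -1.9, 1.0), dlc_sdlog = c(0.4, 0.5, 0.5))
}

#' Simulate ACL and DLC sensor streams from latent states
#'
#' @param states `latent_states` object.
#' @param profile `sensor_profile`.
#' @param seed integer seed.
#' @return list with elements `acl` and `dlc`, each a [sensor_series()].
#' @export
simulate_sensors <- function(states, profile = default_sensor_profile(),
                             seed = 1) {
  stopifnot(inherits(states, "latent_states"),
            inherits(profile, "sensor_profile"))
  s <- states$states
  set.seed(child_seed(seed, "acl"))
  acl <- rlnorm(length(s), profile$acl_meanlog[s], profile$acl_sdlog[s])
  set.seed(child_seed(seed, "dlc"))
  dlc <- rlnorm(length(s), profile$dlc_meanlog[s], profile$dlc_sdlog[s])
  list(acl = sensor_series(acl, dt = states$step_duration, units = "a.u."),
       dlc = sensor_series(dlc, dt = states$step_duration, units = "px/s"))
}

#' Per-state oscillatory LFP profile
#'
#' Parameterizes the synthetic LFP: per-state band amplitudes (mV), per-state
#' phase-amplitude coupling strength, per-channel preferred coupling angle,
#' background 1/f noise level, and a planted VAR structure for directed
#' interactions.
#'
#' @param delta_amp,gamma_amp,high_gamma_amp per-state amplitudes (mV).
#' @param pac_strength per-state coupling strength in `[0, 1]`.
#' @param pac_angle per-channel preferred delta phase in `(-pi, pi]` (radians;
#'   0 = delta peak, cosine convention).
#' @param delta_freq delta oscillation frequency in Hz.
#' @param background 1/f background noise RMS (mV).
#' @param var_coefficients list of lag coefficient matrices
#'   (`channels x channels`), row = target, column = source.
#' @param noise_cov innovation covariance of the VAR component (mV^2).
#' @param channels channel names.
#' @return object of class `lfp_profile`.
#' @export
lfp_profile <- function(delta_amp, gamma_amp, high_gamma_amp, pac_strength,
                        pac_angle, delta_freq = 2, background = 0.05,
                        var_coefficients = NULL, noise_cov = NULL,
                        channels = c("VP", "MD", "AC", "V1")) {
  nc <- length(channels)
  if (any(delta_amp < 0) || any(gamma_amp < 0) || any(high_gamma_amp < 0))
    stop_invalid("band amplitudes must be >= 0")
  if (any(pac_strength < 0) || any(pac_strength > 1))
    stop_invalid("pac_strength must lie in [0, 1]")
  if (length(pac_angle) != nc)
    stop_invalid("pac_angle needs one entry per channel")
  if (is.null(var_coefficients))
    var_coefficients <- list(diag(0.25, nc))
  if (is.null(noise_cov)) noise_cov <- diag(0.1^2, nc)
  if (!isTRUE(all.equal(noise_cov, t(noise_cov))) ||
      any(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop_invalid("noise_cov must be symmetric positive definite")
  if (var_spectral_radius(var_coefficients) >= 1)
    stop_invalid("var_coefficients define an unstable VAR ",
                 "(companion spectral radius >= 1)")
  structure(list(delta_amp = delta_amp, gamma_amp = gamma_amp,
                 high_gamma_amp = high_gamma_amp, pac_strength = pac_strength,
                 pac_angle = pac_angle, delta_freq = delta_freq,
                 background = background,
                 var_coefficients = var_coefficients, noise_cov = noise_cov,
                 channels = channels),
            class = "lfp_profile")
}

#' Default LFP profile
#'
#' Band amplitudes follow the qualitative state ordering of home-cage
#' recordings: delta strongest during sleep (slow waves around 2 mV), gamma
#' and high-gamma strongest during DMN behaviors, intermediate during
#' locomotion/exploration, weak during sleep.  Phase-amplitude coupling is
#' strongest in the DMN state; the preferred angle advances across channels
#' (VP earliest in the delta cycle, then MD near -pi/4, then AC).  The VAR
#' component gives every channel a gamma-band resonance (AR(2) poles at
#' 50 Hz, assuming 400 Hz sampling) and plants the directed structure
#' MD->AC, MD->VP, VP->AC through lag-1 coupling between the resonant
#' channels, so the planted interactions are gamma-band specific.
#'
#' @return `lfp_profile` object.
#' @export
default_lfp_profile <- function() {
  ch <- c("VP", "MD", "AC", "V1")
  r <- 0.8
  w0 <- 2 * pi * 50 / 400                  # 50 Hz resonance at fs = 400
  A1 <- diag(2 * r * cos(w0), 4)
  dimnames(A1) <- list(ch, ch)
  A1["VP", "MD"] <- 0.30   # MD -> VP
  A1["AC", "MD"] <- 0.35   # MD -> AC
  A1["AC", "VP"] <- 0.25   # VP -> AC
  A2 <- diag(-r^2, 4)
  dimnames(A2) <- list(ch, ch)
  lfp_profile(delta_amp = c(2.0, 0.5, 0.3),
              gamma_amp = c(0.05, 0.30, 0.15),
              high_gamma_amp = c(0.03, 0.15, 0.08),
              pac_strength = c(0.10, 0.80, 0.40),
              pac_angle = c(VP = -3 * pi / 4, MD = -pi / 4, AC = pi / 4,
                            V1 = 0),
              var_coefficients = list(A1, A2),
              channels = ch)
}

var_companion <- function(coeffs) {
  p <- length(coeffs)
  m <- nrow(coeffs[[1]])
  comp <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) comp[1:m, ((k - 1) * m + 1):(k * m)] <- coeffs[[k]]
  if (p > 1) comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  comp
}

var_spectral_radius <- function(coeffs) {
  max(Mod(eigen(var_companion(coeffs), only.values = TRUE)$values))
}

#' Simulate a stationary VAR process
#'
#' @param coeffs list of lag coefficient matrices (row = target,
#'   column = source).
#' @param sigma innovation covariance.
#' @param n number of samples.
#' @param seed integer seed.
#' @param burn burn-in samples discarded.
#' @return `n x channels` matrix.
#' @export
simulate_var <- function(coeffs, sigma, n, seed = 1, burn = 500) {
  if (var_spectral_radius(coeffs) >= 1)
    stop_invalid("unstable VAR: companion spectral radius >= 1")
  m <- nrow(coeffs[[1]])
  p <- length(coeffs)
  set.seed(child_seed(seed, "var"))
  L <- chol(sigma)
  eps <- matrix(rnorm((n + burn) * m), ncol = m) %*% L
  X <- matrix(0, n + burn, m)
  for (t in seq_len(n + burn)) {
    xt <- eps[t, ]
    for (k in seq_len(p)) {
      if (t > k) xt <- xt + coeffs[[k]] %*% X[t - k, ]
    }
    X[t, ] <- xt
  }
  X[(burn + 1):(burn + n), , drop = FALSE]
}

one_over_f_noise <- function(n, seed_stream, seed, f_floor = 1) {
  set.seed(child_seed(seed, seed_stream))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)                 # two-sided frequency index
  scale <- 1 / sqrt(pmax(f, f_floor))
  x <- Re(fft(W * scale, inverse = TRUE) / n)
  x / sd(x)
}

#' Simulate multichannel LFP with known ground truth
#'
#' Each channel is the sum of (i) a VAR innovation process filtered through
#' the planted coefficient matrices, (ii) a per-state delta sinusoid with
#' phase continuous across state boundaries, (iii) a band-limited Gaussian
#' gamma carrier whose envelope is modulated by the delta phase as
#' `(1 + s * cos(phase - pac_angle)) / (1 + s)` and scaled by the per-state
#' gamma amplitude, (iv) band-limited high-gamma noise, and (v) 1/f
#' background noise.
#'
#' @param states `latent_states` object.
#' @param profile `lfp_profile`.
#' @param fs sampling rate in Hz; must exceed twice the highest band edge
#'   (> 300 Hz for the default 60-150 Hz high-gamma band).
#' @param seed integer seed.
#' @return `n_samples x channels` numeric matrix with attributes `fs`,
#'   `channels`, `state_per_sample`.
#' @export
simulate_lfp <- function(states, profile = default_lfp_profile(), fs = 400,
                         seed = 1) {
  stopifnot(inherits(states, "latent_states"),
            inherits(profile, "lfp_profile"))
  if (fs <= 2 * 150)
    stop_invalid("fs must exceed 300 Hz to carry the high-gamma band")
  spp <- round(states$step_duration * fs)
  n <- length(states$states) * spp
  state_smp <- rep(states$states, each = spp)
  nc <- length(profile$channels)
  tt <- seq_len(n) / fs
  phase <- 2 * pi * profile$delta_freq * tt     # continuous delta phase
  delta_wave <- profile$delta_amp[state_smp] * cos(phase)

  var_part <- simulate_var(profile$var_coefficients, profile$noise_cov, n,
                           seed = child_seed(seed, "lfp_var"))
  out <- matrix(0, n, nc, dimnames = list(NULL, profile$channels))
  for (c_i in seq_len(nc)) {
    set.seed(child_seed(seed, paste0("gamma_carrier_", c_i)))
    carrier <- bandpass(rnorm(n), DEFAULT_BANDS$gamma, fs)
    carrier <- carrier / sd(carrier)
    s <- profile$pac_strength[state_smp]
    env <- (1 + s * cos(phase - profile$pac_angle[c_i])) / (1 + s)
    gamma_comp <- profile$gamma_amp[state_smp] * env * carrier

    set.seed(child_seed(seed, paste0("hgamma_", c_i)))
    hg <- bandpass(rnorm(n), DEFAULT_BANDS$high_gamma, fs)
    hg <- hg / sd(hg) * profile$high_gamma_amp[state_smp]

    bg <- profile$background *
      one_over_f_noise(n, paste0("bg_", c_i), seed)

    out[, c_i] <- delta_wave + gamma_comp + hg + bg + var_part[, c_i]
  }
  attr(out, "fs") <- fs
  attr(out, "channels") <- profile$channels
  attr(out, "state_per_sample") <- state_smp
  out
}

#' Expand a per-step state sequence to per-sample states
#'
#' @param states `latent_states` object.
#' @param fs target sampling rate in Hz.
#' @return integer vector with one state per sample.
#' @export
states_to_samples <- function(states, fs) {
  rep(states$states, each = round(states$step_duration * fs))
}

# ---- external formats -----------------------------------------------------

#' Write a simulated session to disk
#'
#' Sensors and truth labels go to `sensors.csv`
#' (`step_index, acl, dlc, true_state`); the LFP goes to `lfp.f32` as raw
#' little-endian float32, sample-major (all channels of sample 1, then
#' sample 2, ...), with a JSON sidecar `lfp.json` holding
#' `{channels, fs_hz, n_samples}`.
#'
#' @param dir output directory (created if missing).
#' @param states `latent_states`.
#' @param sensors list with `acl`, `dlc` sensor series.
#' @param lfp matrix from [simulate_lfp()] (optional).
#' @return invisibly, the vector of file paths written.
#' @export
write_simulation <- function(dir, states, sensors, lfp = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  sp <- file.path(dir, "sensors.csv")
  write.csv(data.frame(step_index = seq_along(states$states),
                       acl = sensors$acl$values, dlc = sensors$dlc$values,
                       true_state = states$states),
            sp, row.names = FALSE)
  paths <- c(paths, sp)
  if (!is.null(lfp)) {
    bp <- file.path(dir, "lfp.f32")
    con <- file(bp, "wb")
    writeBin(as.numeric(t(lfp)), con, size = 4, endian = "little")
    close(con)
    jp <- file.path(dir, "lfp.json")
    jsonlite::write_json(list(channels = attr(lfp, "channels"),
                              fs_hz = attr(lfp, "fs"),
                              n_samples = nrow(lfp)),
                         jp, auto_unbox = TRUE)
    paths <- c(paths, bp, jp)
  }
  invisible(paths)
}

#' Read an LFP written by [write_simulation()]
#'
#' @param path path to the `.f32` binary; the `.json` sidecar must sit next
#'   to it.
#' @return matrix with attributes `fs`, `channels`.
#' @export
read_lfp_bin <- function(path) {
  sidecar <- sub("\\.f32$", ".json", path)
  if (!file.exists(sidecar)) stop_invalid("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  nc <- length(meta$channels)
  con <- file(path, "rb")
  raw <- readBin(con, numeric(), n = meta$n_samples * nc, size = 4,
                 endian = "little")
  close(con)
  m <- matrix(raw, ncol = nc, byrow = TRUE,
              dimnames = list(NULL, meta$channels))
  attr(m, "fs") <- meta$fs_hz
  attr(m, "channels") <- meta$channels
  m
}
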