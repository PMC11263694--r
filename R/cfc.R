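# Delta-phase -> gamma-amplitude cross-frequency coupling: band-pass
# filtering, analytic phase/amplitude, and the amplitude-weighted circular
# mean coupling vector.

#' Phase and amplitude series from band-filtered signals
#'
#' Phase is the angle of the analytic signal of the low-frequency band
#' (cosine convention: 0 at the wave peak, +/- pi at the trough); amplitude
#' is the modulus of the analytic signal of the high-frequency band.  A
#' fraction of samples at each edge is discarded to suppress filter
#' transients.
#'
#' @param filtered_low,filtered_high equal-length filtered signals.
#' @param trim fraction of samples discarded at each edge (default 0.05).
#' @return list with `phase`, `amplitude`, and `index` (positions kept in
#'   the original series).
#' @export
analytic_phase_amplitude <- function(filtered_low, filtered_high,
                                     trim = 0.05) {
  n <- length(filtered_low)
  if (length(filtered_high) != n)
    stop_invalid("low- and high-band series differ in length")
  phase <- Arg(analytic_signal(filtered_low))
  amplitude <- Mod(analytic_signal(filtered_high))
  cut <- floor(n * trim)
  keep <- if (cut > 0) (cut + 1):(n - cut) else seq_len(n)
  list(phase = phase[keep], amplitude = amplitude[keep], index = keep)
}

#' Phase-amplitude coupling vector
#'
#' The amplitude-weighted circular mean
#' `v = sum(a * exp(1i * phi)) / sum(a)`: `strength = |v|` lies in `[0, 1]`,
#' `angle = Arg(v)` is the preferred phase.  With `weight = "power"` the
#' squared amplitude is used as the weight instead.
#'
#' @param phase numeric radians.
#' @param amplitude non-negative weights, same length.
#' @param weight `"amplitude"` (default) or `"power"`.
#' @return object of class `cfc_vector`: list with `strength`, `angle`,
#'   `n_samples`.
#' @export
cfc_vector <- function(phase, amplitude, weight = c("amplitude", "power")) {
  weight <- match.arg(weight)
  if (length(phase) != length(amplitude))
    stop_invalid("phase and amplitude differ in length")
  if (any(amplitude < 0)) stop_invalid("amplitudes must be >= 0")
  w <- if (weight == "power") amplitude^2 else amplitude
  tot <- sum(w)
  if (tot == 0) stop_invalid("undefined coupling vector: all-zero amplitude")
  v <- sum(w * exp(1i * phase)) / tot
  structure(list(strength = Mod(v), angle = Arg(v),
                 n_samples = length(phase)),
            class = "cfc_vector")
}

#' @export
print.cfc_vector <- function(x, ...) {
  cat(sprintf("cfc_vector: strength %.3f, angle %.3f rad (n = %d)\n",
              x$strength, x$angle, x$n_samples))
  invisible(x)
}

#' Per-state phase-amplitude coupling for one LFP channel
#'
#' Filtering and the Hilbert transform run on the continuous signal first;
#' samples are then pooled by behavioral state before the coupling vector is
#' computed.  States with under `min_seconds` of data are flagged
#' `reliable = FALSE` (not an error).
#'
#' @param lfp `samples x channels` matrix (with `fs` attribute) or vector.
#' @param states per-sample integer states, or a `latent_states` /
#'   `state_path` object (expanded at `fs`).
#' @param channel channel index or name.
#' @param fs sampling rate in Hz (default from the `fs` attribute).
#' @param low_band,high_band phase- and amplitude-providing bands in Hz.
#' @param trim edge fraction discarded after filtering.
#' @param weight passed to [cfc_vector()].
#' @param min_seconds reliability floor per state (default 2).
#' @return data frame: `state`, `strength`, `angle`, `n_samples`,
#'   `reliable`.
#' @export
cfc_by_state <- function(lfp, states, channel = 1, fs = attr(lfp, "fs"),
                         low_band = DEFAULT_BANDS$delta,
                         high_band = DEFAULT_BANDS$gamma, trim = 0.05,
                         weight = "amplitude", min_seconds = 2) {
  if (is.null(dim(lfp))) lfp <- matrix(lfp, ncol = 1)
  if (is.null(fs)) stop_invalid("fs must be given (or attached to the lfp)")
  if (is.character(channel)) channel <- match(channel, colnames(lfp))
  x <- lfp[, channel]
  if (inherits(states, c("latent_states", "state_path"))) {
    states <- rep(states$states, each = round(states$step_duration * fs))
  }
  states <- states[seq_len(min(length(states), length(x)))]
  x <- x[seq_len(length(states))]
  pa <- analytic_phase_amplitude(bandpass(x, low_band, fs),
                                 bandpass(x, high_band, fs), trim = trim)
  st <- states[pa$index]
  ks <- sort(unique(st))
  rows <- lapply(ks, function(k) {
    sel <- st == k
    v <- cfc_vector(pa$phase[sel], pa$amplitude[sel], weight = weight)
    data.frame(state = k, strength = v$strength, angle = v$angle,
               n_samples = v$n_samples,
               reliable = v$n_samples >= min_seconds * fs)
  })
  do.call(rbind, rows)
}
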