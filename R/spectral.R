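# Epoching, per-epoch Hann periodograms, band power, delta amplitude and the
# high-delta epoch rule.

#' Partition a multichannel LFP into fixed-length epochs
#'
#' Non-overlapping epochs; a trailing partial epoch is dropped.  The epoch
#' array is per-epoch demeaned for spectral analysis; the untouched
#' continuous signal (trimmed to whole epochs) is kept alongside so that
#' narrow-band filtering can run on the continuous data and avoid per-epoch
#' edge artifacts.
#'
#' @param lfp numeric matrix `samples x channels` (a vector is treated as one
#'   channel); an `fs` attribute is honored.
#' @param fs sampling rate in Hz.
#' @param epoch_length epoch length in seconds (default 0.5).
#' @return object of class `epoched_lfp` with fields `array`
#'   (`epochs x channels x samples`, demeaned), `signal` (continuous,
#'   trimmed), `fs`, `epoch_length`, `n_epochs`, `channels`.
#' @export
epoch_signal <- function(lfp, fs = attr(lfp, "fs"), epoch_length = 0.5) {
  if (is.null(dim(lfp))) lfp <- matrix(lfp, ncol = 1)
  if (is.null(fs)) stop_invalid("fs must be given (or attached to the lfp)")
  spe <- as.integer(round(epoch_length * fs))
  if (spe < 8) stop_invalid("epoch too short: ", spe, " samples (need >= 8)")
  n <- nrow(lfp)
  if (n < spe) stop_invalid("epoch (", spe, " samples) longer than signal (",
                            n, " samples)")
  if (anyNA(lfp)) stop_invalid("LFP contains NA/NaN")
  n_ep <- as.integer(n %/% spe)
  nc <- ncol(lfp)
  trimmed <- lfp[seq_len(n_ep * spe), , drop = FALSE]
  arr <- array(NA_real_, dim = c(n_ep, nc, spe))
  for (c_i in seq_len(nc)) {
    m <- matrix(trimmed[, c_i], nrow = spe)       # samples x epochs
    m <- sweep(m, 2, colMeans(m))                 # per-epoch demean
    arr[, c_i, ] <- t(m)
  }
  channels <- colnames(lfp) %||% paste0("ch", seq_len(nc))
  structure(list(array = arr, signal = trimmed, fs = fs,
                 epoch_length = epoch_length, n_epochs = n_ep,
                 samples_per_epoch = spe, channels = channels),
            class = "epoched_lfp")
}

#' @export
print.epoched_lfp <- function(x, ...) {
  cat(sprintf("epoched_lfp: %d epochs x %d channels x %d samples (%g s at %g Hz)\n",
              x$n_epochs, length(x$channels), x$samples_per_epoch,
              x$epoch_length, x$fs))
  invisible(x)
}

# One-sided Hann-tapered power spectral density (units^2/Hz) for each epoch
# of one channel.  Rows = frequency bins 0..fs/2, columns = epochs.
epoch_psd <- function(epoched, channel) {
  spe <- epoched$samples_per_epoch
  m <- t(epoched$array[, channel, , drop = TRUE])
  if (epoched$n_epochs == 1) m <- matrix(m, nrow = spe)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(spe) / spe))  # Hann (periodic)
  U <- sum(w^2)
  X <- stats::mvfft(m * w)
  nb <- floor(spe / 2) + 1
  P <- (Mod(X[seq_len(nb), , drop = FALSE])^2) / (epoched$fs * U)
  # one-sided: double everything except DC (and Nyquist when spe is even)
  dbl <- rep(2, nb); dbl[1] <- 1
  if (spe %% 2 == 0) dbl[nb] <- 1
  P * dbl
}

psd_freqs <- function(epoched) {
  spe <- epoched$samples_per_epoch
  (seq_len(floor(spe / 2) + 1) - 1) * epoched$fs / spe
}

#' Per-epoch, per-channel band power
#'
#' Hann-tapered periodogram per epoch; band power is the mean of the
#' one-sided power spectral density over the bins with
#' `f_lo <= f < f_hi` (half-open, so a shared edge is counted once).
#'
#' @param epoched [epoch_signal()] result.
#' @param band `c(f_lo, f_hi)` in Hz.
#' @return matrix `epochs x channels` (units^2/Hz).
#' @export
band_power <- function(epoched, band) {
  stopifnot(inherits(epoched, "epoched_lfp"))
  if (length(band) != 2 || band[2] <= band[1])
    stop_invalid("band must be c(f_lo, f_hi) with f_lo < f_hi")
  if (band[2] > epoched$fs / 2 + 1e-9)
    stop_invalid("band upper edge ", band[2], " Hz exceeds Nyquist (",
                 epoched$fs / 2, " Hz)")
  f <- psd_freqs(epoched)
  keep <- f >= band[1] & f < band[2]
  if (!any(keep))
    stop_invalid("band (", band[1], ", ", band[2], ") contains no FFT bin ",
                 "at resolution ", f[2], " Hz")
  out <- vapply(seq_along(epoched$channels), function(c_i) {
    colMeans(epoch_psd(epoched, c_i)[keep, , drop = FALSE])
  }, numeric(epoched$n_epochs))
  out <- matrix(out, nrow = epoched$n_epochs,
                dimnames = list(NULL, epoched$channels))
  out
}

#' Per-epoch delta amplitude
#'
#' Mean Hilbert envelope of the delta-band-passed signal within each epoch.
#' Filtering runs on the continuous signal before epoch slicing so that
#' per-epoch filter transients do not corrupt the estimate.
#'
#' @param epoched [epoch_signal()] result.
#' @param band delta band in Hz (default 0.5-4).
#' @return matrix `epochs x channels` of amplitudes (same units as the
#'   signal, typically mV).
#' @export
delta_amplitude <- function(epoched, band = DEFAULT_BANDS$delta) {
  stopifnot(inherits(epoched, "epoched_lfp"))
  spe <- epoched$samples_per_epoch
  out <- vapply(seq_along(epoched$channels), function(c_i) {
    filt <- bandpass(epoched$signal[, c_i], band, epoched$fs)
    env <- Mod(analytic_signal(filt))
    colMeans(matrix(env, nrow = spe))
  }, numeric(epoched$n_epochs))
  matrix(out, nrow = epoched$n_epochs,
         dimnames = list(NULL, epoched$channels))
}

#' High-delta epochs by the midrange rule
#'
#' The threshold is `min + (max - min) / 2` of the per-epoch delta
#' amplitudes over the session; an epoch is high-delta iff its amplitude
#' strictly exceeds the threshold.
#'
#' @param delta_amp numeric vector of per-epoch delta amplitudes (one
#'   channel).
#' @return list with logical `mask` and the numeric `threshold`.
#' @export
high_delta_epochs <- function(delta_amp) {
  delta_amp <- as.numeric(delta_amp)
  if (length(delta_amp) < 2) stop_invalid("need at least 2 epochs")
  thr <- min(delta_amp) + (max(delta_amp) - min(delta_amp)) / 2
  list(mask = delta_amp > thr, threshold = thr)
}

#' Mean band power by behavioral state
#'
#' Joins a per-epoch band-power matrix with a per-epoch state assignment
#' (decoded or ground truth); epochs and steps must share the same timebase.
#'
#' @param bp matrix from [band_power()].
#' @param states integer vector, one state per epoch (may be longer; it is
#'   truncated to the epoch count).
#' @return matrix `states x channels` of mean powers.
#' @export
band_power_by_state <- function(bp, states) {
  states <- states[seq_len(nrow(bp))]
  ks <- sort(unique(states))
  out <- matrix(NA_real_, length(ks), ncol(bp),
                dimnames = list(paste0("state", ks), colnames(bp)))
  for (i in seq_along(ks))
    out[i, ] <- colMeans(bp[states == ks[i], , drop = FALSE])
  out
}
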