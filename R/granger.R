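# VAR fitting by least squares on the lag regression, AIC order selection,
# time-domain conditional Granger causality (two-model refit) and Geweke
# frequency-domain GC with band averages, plus F-test / Benjamini-Hochberg
# significance.  Data may be a single matrix or a list of contiguous
# segments; lag windows never straddle segment boundaries, which is how
# state-conditioned (non-contiguous) epochs are handled.

as_segments <- function(X) {
  if (is.list(X) && !is.data.frame(X)) {
    lapply(X, function(x) {
      x <- as.matrix(x)
      storage.mode(x) <- "double"
      x
    })
  } else {
    x <- as.matrix(X)
    storage.mode(x) <- "double"
    list(x)
  }
}

# Stacked lag regression over segments: returns response Y (rows x m) and
# regressors Z (rows x m*p, lag-major: lag 1 channels, lag 2 channels, ...).
build_lag_regression <- function(segments, p, drop_first = p) {
  Ys <- list(); Zs <- list()
  for (seg in segments) {
    n <- nrow(seg)
    if (n <= drop_first) next
    rows <- (drop_first + 1):n
    Ys[[length(Ys) + 1]] <- seg[rows, , drop = FALSE]
    Z <- do.call(cbind, lapply(seq_len(p), function(k)
      seg[rows - k, , drop = FALSE]))
    Zs[[length(Zs) + 1]] <- Z
  }
  if (!length(Ys)) stop_invalid("no segment long enough for order ", p)
  list(Y = do.call(rbind, Ys), Z = do.call(rbind, Zs))
}

#' Fit a VAR model by least squares
#'
#' Ordinary least squares on the stacked lag regression (the maximum
#' likelihood solution for Gaussian innovations).  Channels are demeaned
#' first; the innovation covariance is the residual cross-product divided by
#' the number of regression rows.
#'
#' @param X `samples x channels` matrix, or a list of such matrices
#'   (contiguous segments; lags never straddle segments).
#' @param p model order in samples (>= 1).
#' @return object of class `var_model`: `p`, `coeffs` (list of
#'   `channels x channels` matrices, row = target, column = source), `Sigma`,
#'   `n_obs` (regression rows), `rss` (per-channel residual sum of squares),
#'   `channels`.
#' @export
fit_var <- function(X, p) {
  if (p < 1) stop_invalid("VAR order p must be >= 1")
  segments <- lapply(as_segments(X), function(seg)
    sweep(seg, 2, colMeans(seg)))
  m <- ncol(segments[[1]])
  reg <- build_lag_regression(segments, p)
  ZtZ <- crossprod(reg$Z)
  cond <- tryCatch(rcond(ZtZ), error = function(e) 0)
  if (!is.finite(cond) || cond < 1e-14)
    stop_invalid("singular regressor matrix in VAR fit (order ", p, ")")
  Bhat <- solve(ZtZ, crossprod(reg$Z, reg$Y))    # (m*p) x m
  resid <- reg$Y - reg$Z %*% Bhat
  n_obs <- nrow(reg$Y)
  Sigma <- crossprod(resid) / n_obs
  coeffs <- lapply(seq_len(p), function(k)
    t(Bhat[((k - 1) * m + 1):(k * m), , drop = FALSE]))
  channels <- colnames(segments[[1]]) %||% paste0("ch", seq_len(m))
  structure(list(p = p, coeffs = coeffs, Sigma = Sigma, n_obs = n_obs,
                 rss = colSums(resid^2), channels = channels),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) on %d channels, %d observations\n", x$p,
              length(x$channels), x$n_obs))
  invisible(x)
}

#' Select VAR order by AIC
#'
#' Evaluates orders `1..round(max_order_ms * fs / 1000)` on a common sample
#' (the first `p_max` samples of each segment are excluded for every
#' candidate) and returns the AIC-minimizing order.  AIC per candidate is
#' `log det(Sigma) + 2 * p * m^2 / n`.
#'
#' @param X matrix or list of segment matrices.
#' @param fs sampling rate in Hz.
#' @param max_order_ms maximum model order in milliseconds (default 20).
#' @return list with `p` (selected order), `aic` (vector over candidates),
#'   `candidates`.
#' @export
select_order <- function(X, fs, max_order_ms = 20) {
  p_max <- round(max_order_ms * fs / 1000)
  if (p_max < 1) stop_invalid("max_order_ms too small at this sampling rate")
  segments <- lapply(as_segments(X), function(seg)
    sweep(seg, 2, colMeans(seg)))
  m <- ncol(segments[[1]])
  aic <- vapply(seq_len(p_max), function(p) {
    reg <- build_lag_regression(segments, p, drop_first = p_max)
    Bhat <- solve(crossprod(reg$Z), crossprod(reg$Z, reg$Y))
    resid <- reg$Y - reg$Z %*% Bhat
    n <- nrow(reg$Y)
    Sigma <- crossprod(resid) / n
    as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
      2 * p * m^2 / n
  }, numeric(1))
  list(p = which.min(aic), aic = aic, candidates = seq_len(p_max))
}

# VAR transfer function H(f) = (I - sum_k A_k e^{-2 pi i f k / fs})^{-1}
var_transfer_at <- function(coeffs, f, fs) {
  m <- nrow(coeffs[[1]])
  A <- diag(m) + 0i
  for (k in seq_along(coeffs))
    A <- A - coeffs[[k]] * exp(-2i * pi * f * k / fs)
  solve(A)
}

#' Time-domain conditional Granger causality
#'
#' Two-model refit: the full VAR over `target, source, conditioning` and the
#' reduced VAR omitting the source.  `F = log(Sigma_reduced[target] /
#' Sigma_full[target])`; negative estimates are floored at 0 and flagged.
#'
#' @param X matrix or list of segment matrices.
#' @param source,target channel indices or names (distinct).
#' @param conditioning channel indices/names excluded from both roles
#'   (possibly empty).
#' @param p VAR order of the full model.
#' @param p_reduced VAR order of the reduced model.  Defaults to `p`, which
#'   keeps the two models nested so the parametric F-test applies.  The
#'   marginal process of a VAR is generally VARMA, so a larger `p_reduced`
#'   approximates it better and tightens the Geweke spectral-integral
#'   identity; use that when the spectral decomposition, not the F-test, is
#'   the goal.
#' @return object of class `gc_result` with `F_time`, `p_value` inputs
#'   (`rss_full`, `rss_reduced`, `df1`, `df2`), `floored` flag.
#' @export
gc_time_conditional <- function(X, source, target, conditioning = integer(0),
                                p, p_reduced = p) {
  segs <- as_segments(X)
  channels <- colnames(segs[[1]]) %||% paste0("ch", seq_len(ncol(segs[[1]])))
  idx <- function(ch) if (is.character(ch)) match(ch, channels) else as.integer(ch)
  src <- idx(source); tgt <- idx(target); cnd <- idx(conditioning)
  if (anyNA(c(src, tgt, cnd))) stop_invalid("unknown channel name")
  if (src == tgt) stop_invalid("source and target must differ")
  if (any(c(src, tgt) %in% cnd))
    stop_invalid("conditioning set must exclude source and target")
  full_ch <- c(tgt, src, cnd)
  red_ch <- c(tgt, cnd)
  full <- fit_var(lapply(segs, function(s) s[, full_ch, drop = FALSE]), p)
  red <- fit_var(lapply(segs, function(s) s[, red_ch, drop = FALSE]),
                 p_reduced)
  Fv <- log(red$Sigma[1, 1] / full$Sigma[1, 1])
  floored <- Fv < 0
  structure(list(source = channels[src], target = channels[tgt],
                 conditioning = channels[cnd], F_time = max(Fv, 0),
                 floored = floored, nested = p_reduced == p,
                 rss_full = full$rss[1], rss_reduced = red$rss[1],
                 df1 = p, df2 = full$n_obs - length(full_ch) * p,
                 n_obs = full$n_obs, full = full, reduced = red),
            class = "gc_result")
}

#' Spectral (Geweke) conditional Granger causality
#'
#' Frequency-domain GC from the fitted VAR transfer function with
#' innovation-covariance normalization.  With an empty conditioning set this
#' is the classic bivariate Geweke decomposition; otherwise the conditional
#' formulation is used: the reduced VAR (target + conditioning) is refit, its
#' transfer function is embedded alongside an identity row for the source,
#' and the conditional spectrum follows from `Q(f) = Gbar(f)^{-1} Htilde(f)`.
#' The time-domain value satisfies the Geweke integral identity
#' `F_time ~ (1/pi) * integral of GC(f) d omega` up to estimation error.
#'
#' @inheritParams gc_time_conditional
#' @param fs sampling rate in Hz.
#' @param freqs frequency grid in Hz (default 0 to Nyquist in 0.5 Hz steps).
#' @param bands named list of bands for band averages (default delta, gamma,
#'   high-gamma).
#' @return `gc_result` with additionally `freqs`, `spectrum`, `band_means`.
#' @export
gc_spectral <- function(X, source, target, conditioning = integer(0), p, fs,
                        freqs = seq(0, fs / 2, by = 0.5),
                        bands = DEFAULT_BANDS, p_reduced = p) {
  res <- gc_time_conditional(X, source, target, conditioning, p, p_reduced)
  full <- res$full
  red <- res$reduced
  if (var_spectral_radius(full$coeffs) >= 1)
    stop_invalid("fitted VAR is unstable; try a lower order than ", p)
  m <- length(full$channels)
  Sigma <- full$Sigma
  # normalization: remove correlation between the target innovation and the
  # rest, leaving Sigma[1,1] unchanged
  P <- diag(m)
  if (m > 1) P[2:m, 1] <- -Sigma[2:m, 1] / Sigma[1, 1]
  Pinv <- diag(m)
  if (m > 1) Pinv[2:m, 1] <- Sigma[2:m, 1] / Sigma[1, 1]
  Sig_t <- P %*% Sigma %*% t(P)
  mr <- m - 1                      # reduced system dimension
  gc <- vapply(freqs, function(f) {
    H <- var_transfer_at(full$coeffs, f, fs)
    Ht <- H %*% Pinv
    if (length(res$conditioning) == 0) {
      S11 <- Re((H %*% Sigma %*% Conj(t(H)))[1, 1])
      intr <- S11 - Re(Sig_t[2, 2] * Mod(Ht[1, 2])^2)
      log(S11 / max(intr, .Machine$double.eps))
    } else {
      G <- var_transfer_at(red$coeffs, f, fs)
      Gbar <- matrix(0i, m, m)
      ri <- c(1, 3:m)              # reduced vars sit at full positions 1,3..m
      Gbar[ri, ri] <- G
      Gbar[2, 2] <- 1
      Q <- solve(Gbar) %*% Ht
      log(red$Sigma[1, 1] / max(Re(Mod(Q[1, 1])^2 * Sig_t[1, 1]),
                                .Machine$double.eps))
    }
  }, numeric(1))
  band_means <- vapply(bands, function(b) {
    keep <- freqs >= b[1] & freqs < b[2]
    if (!any(keep)) return(NA_real_)
    max(mean(gc[keep]), 0)
  }, numeric(1))
  res$freqs <- freqs
  res$spectrum <- gc
  res$band_means <- band_means
  res
}

#' F-test and FDR adjustment for a family of GC results
#'
#' Parametric F-test per direction from the full/reduced residual sums of
#' squares, then Benjamini-Hochberg adjustment across the family; a
#' direction is significant iff `q < Q`.
#'
#' @param results list of `gc_result` objects.
#' @param Q false-discovery-rate level (default 0.05).
#' @return data frame with source, target, F_time, band means (if present),
#'   `p_value`, `q_value`, `significant`.
#' @export
gc_significance <- function(results, Q = 0.05) {
  stopifnot(length(results) >= 1)
  pvals <- vapply(results, function(r) {
    fstat <- ((r$rss_reduced - r$rss_full) / r$df1) / (r$rss_full / r$df2)
    pf(max(fstat, 0), r$df1, r$df2, lower.tail = FALSE)
  }, numeric(1))
  qvals <- p.adjust(pvals, method = "BH")
  df <- data.frame(
    source = vapply(results, `[[`, character(1), "source"),
    target = vapply(results, `[[`, character(1), "target"),
    F_time = vapply(results, `[[`, numeric(1), "F_time"),
    p_value = pvals, q_value = qvals, significant = qvals < Q,
    stringsAsFactors = FALSE)
  bm <- lapply(results, function(r) r$band_means)
  if (all(!vapply(bm, is.null, logical(1)))) {
    bmat <- do.call(rbind, bm)
    colnames(bmat) <- paste0("gc_", colnames(bmat) %||%
                               names(results[[1]]$band_means))
    df <- cbind(df, bmat)
  }
  rownames(df) <- NULL
  df
}

#' All-pairs conditional GC table
#'
#' Computes spectral conditional GC for every ordered channel pair,
#' conditioning on all remaining channels, and attaches F-test/FDR
#' significance.
#'
#' @param X matrix or list of segment matrices.
#' @param fs sampling rate in Hz.
#' @param p VAR order; selected by AIC when `NULL`.
#' @param conditional condition each pair on the remaining channels
#'   (default TRUE); otherwise pairwise unconditional.
#' @param Q FDR level.
#' @param bands named band list.
#' @param max_order_ms passed to [select_order()] when `p` is `NULL`.
#' @return data frame (one row per direction) from [gc_significance()],
#'   with the selected order as attribute `p`.
#' @export
gc_table <- function(X, fs, p = NULL, conditional = TRUE, Q = 0.05,
                     bands = DEFAULT_BANDS, max_order_ms = 20) {
  segs <- as_segments(X)
  m <- ncol(segs[[1]])
  channels <- colnames(segs[[1]]) %||% paste0("ch", seq_len(m))
  if (is.null(p)) p <- select_order(segs, fs, max_order_ms)$p
  results <- list()
  for (src in seq_len(m)) for (tgt in seq_len(m)) {
    if (src == tgt) next
    cnd <- if (conditional) setdiff(seq_len(m), c(src, tgt)) else integer(0)
    results[[length(results) + 1]] <-
      gc_spectral(segs, src, tgt, cnd, p, fs, bands = bands)
  }
  out <- gc_significance(results, Q = Q)
  out$source <- channels[match(out$source, channels)]
  attr(out, "p") <- p
  out
}

#' Split samples into contiguous same-state segments
#'
#' Helper for state-conditioned GC: returns, for one state, the list of
#' maximal contiguous sample runs (so VAR lags never straddle a state
#' boundary).
#'
#' @param lfp `samples x channels` matrix.
#' @param state_per_sample integer vector, one state per sample.
#' @param state which state to keep.
#' @param min_len drop runs shorter than this many samples (default 2).
#' @return list of matrices.
#' @export
state_segments <- function(lfp, state_per_sample, state, min_len = 2) {
  stopifnot(nrow(lfp) == length(state_per_sample))
  r <- rle(state_per_sample == state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_len)
  lapply(keep, function(i) lfp[starts[i]:ends[i], , drop = FALSE])
}
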