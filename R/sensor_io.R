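# Pose-table and accelerometer ingestion: derive nose speed and movement
# magnitude on a common timebase for symbolization.

#' Uniformly sampled scalar sensor series
#'
#' @param values non-negative numeric values.
#' @param dt sampling interval in seconds.
#' @param origin_time time of the first sample in seconds.
#' @param units unit label.
#' @return object of class `sensor_series`.
#' @export
sensor_series <- function(values, dt, origin_time = 0, units = "a.u.") {
  values <- as.numeric(values)
  if (dt <= 0) stop_invalid("dt must be > 0")
  if (anyNA(values)) stop_invalid("sensor series must be NaN-free")
  if (any(values < 0)) stop_invalid("sensor values must be >= 0")
  structure(list(values = values, dt = dt, origin_time = origin_time,
                 units = units),
            class = "sensor_series")
}

#' @export
print.sensor_series <- function(x, ...) {
  cat(sprintf("sensor_series: %d samples at dt = %g s (%s)\n",
              length(x$values), x$dt, x$units))
  invisible(x)
}

#' @export
length.sensor_series <- function(x) length(x$values)

#' Read a pose-tracking table (3-header-row CSV dialect)
#'
#' The expected layout is the standard markerless-pose-estimation export:
#' a `scorer` row, a `bodyparts` row, a `coords` row (`x`, `y`,
#' `likelihood` per body part), then one row per frame with the frame index
#' in the first column.
#'
#' @param path CSV file path.
#' @param fps video frame rate (frames/s); the 2 fps used for home-cage
#'   video is the default.
#' @return object of class `pose_track`: list of per-bodypart data frames
#'   (`x`, `y`, `likelihood`) plus `fps`, `bodyparts`, `n_frames`.
#' @export
read_pose_table <- function(path, fps = 2) {
  raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character")
  if (nrow(raw) < 3)
    stop_invalid("pose table needs scorer/bodyparts/coords header rows; ",
                 "file has only ", nrow(raw), " rows")
  hdr_bp <- as.character(raw[2, -1])
  hdr_co <- as.character(raw[3, -1])
  if (tolower(as.character(raw[2, 1])) != "bodyparts")
    stop_invalid("malformed header: row 2 must be the 'bodyparts' row, got '",
                 as.character(raw[2, 1]), "'")
  if (tolower(as.character(raw[3, 1])) != "coords")
    stop_invalid("malformed header: row 3 must be the 'coords' row, got '",
                 as.character(raw[3, 1]), "'")
  bodyparts <- unique(hdr_bp)
  body <- raw[-(1:3), , drop = FALSE]
  n_frames <- nrow(body)
  track <- list()
  for (bp in bodyparts) {
    cols <- which(hdr_bp == bp)
    have <- hdr_co[cols]
    need <- c("x", "y", "likelihood")
    if (!all(need %in% have))
      stop_invalid("bodypart '", bp, "' is missing column(s): ",
                   paste(setdiff(need, have), collapse = ", "))
    get <- function(name) as.numeric(body[[cols[which(have == name)[1]] + 1L]])
    df <- data.frame(x = get("x"), y = get("y"),
                     likelihood = get("likelihood"))
    if (any(df$likelihood < 0 | df$likelihood > 1, na.rm = TRUE))
      stop_invalid("bodypart '", bp, "': likelihood outside [0, 1]")
    track[[bp]] <- df
  }
  structure(list(parts = track, fps = fps, bodyparts = bodyparts,
                 n_frames = n_frames),
            class = "pose_track")
}

#' Write a pose-tracking table in the 3-header-row dialect
#'
#' Counterpart of [read_pose_table()], used to build fixtures and round-trip
#' checks.
#'
#' @param track `pose_track` object.
#' @param path output CSV path.
#' @param scorer scorer name written in the first header row.
#' @return invisibly, `path`.
#' @export
write_pose_table <- function(track, path, scorer = "synthetic") {
  stopifnot(inherits(track, "pose_track"))
  coords <- c("x", "y", "likelihood")
  hdr1 <- c("scorer", rep(scorer, 3 * length(track$bodyparts)))
  hdr2 <- c("bodyparts", rep(track$bodyparts, each = 3))
  hdr3 <- c("coords", rep(coords, length(track$bodyparts)))
  body <- do.call(cbind, lapply(track$parts, function(df)
    as.matrix(df[, coords])))
  body <- cbind(seq_len(track$n_frames) - 1L, body)
  con <- file(path, "w")
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  write.table(body, con, sep = ",", col.names = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Nose (or other bodypart) speed from a pose track
#'
#' Speed is the Euclidean distance between positions on subsequent frames
#' times the frame rate (px/s).  Frames whose likelihood falls below
#' `likelihood_min` have their coordinates linearly interpolated from the
#' nearest confident neighbors before differencing.  The first value is
#' duplicated so the series has one value per frame.
#'
#' @param track `pose_track` object.
#' @param bodypart which body part to track (default `"nose"`).
#' @param likelihood_min confidence threshold in `[0, 1]` below which frames
#'   are treated as missing (default 0.9).
#' @return [sensor_series()] in px/s with `dt = 1/fps`.
#' @export
compute_speed <- function(track, bodypart = "nose", likelihood_min = 0.9) {
  stopifnot(inherits(track, "pose_track"))
  if (!bodypart %in% track$bodyparts)
    stop_invalid("bodypart '", bodypart, "' not in track (has: ",
                 paste(track$bodyparts, collapse = ", "), ")")
  df <- track$parts[[bodypart]]
  if (nrow(df) < 2) stop_invalid("need at least 2 frames to compute speed")
  ok <- df$likelihood >= likelihood_min & is.finite(df$x) & is.finite(df$y)
  if (!any(ok))
    stop_invalid("unusable track: no frame reaches likelihood ",
                 likelihood_min)
  idx <- seq_len(nrow(df))
  x <- df$x; y <- df$y
  if (!all(ok)) {
    x <- approx(idx[ok], x[ok], xout = idx, rule = 2)$y
    y <- approx(idx[ok], y[ok], xout = idx, rule = 2)$y
  }
  d <- sqrt(diff(x)^2 + diff(y)^2) * track$fps
  sensor_series(c(d[1], d), dt = 1 / track$fps, units = "px/s")
}

#' Accelerometer movement magnitude
#'
#' Removes the gravity component from each axis with a zero-phase high-pass
#' filter, then takes the per-sample Euclidean norm across the three axes.
#'
#' @param xyz 3-column matrix (or data frame) of axis samples.
#' @param fs sampling rate in Hz.
#' @param highpass_hz high-pass cutoff (default 1 Hz, 4th-order Butterworth,
#'   applied forward-backward).
#' @return [sensor_series()] with `dt = 1/fs`.
#' @export
accel_magnitude <- function(xyz, fs = 400, highpass_hz = 1) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop_invalid("xyz must have exactly 3 axis columns")
  if (anyNA(xyz)) stop_invalid("accelerometer data must be NaN-free")
  if (fs <= 2 * highpass_hz)
    stop_invalid("fs must exceed twice the high-pass cutoff")
  filt <- apply(xyz, 2, highpass, cutoff = highpass_hz, fs = fs)
  mag <- sqrt(rowSums(filt^2))
  sensor_series(mag, dt = 1 / fs, units = "a.u.")
}

#' Reduce a sensor series to a coarser step
#'
#' Non-overlapping windows of length `step` are reduced by RMS (default; the
#' energy of head vibration, not its sign, carries behavioral information) or
#' by the mean.  A trailing partial window is dropped.
#'
#' @param series [sensor_series()].
#' @param step target step in seconds (`>= series$dt`).
#' @param reducer `"rms"` or `"mean"`.
#' @return [sensor_series()] with `dt = step`.
#' @export
resample_to_steps <- function(series, step, reducer = c("rms", "mean")) {
  stopifnot(inherits(series, "sensor_series"))
  reducer <- match.arg(reducer)
  if (step < series$dt - 1e-12)
    stop_invalid("step (", step, " s) must be >= series dt (", series$dt,
                 " s)")
  n_per <- floor(step / series$dt + 1e-9)
  n_win <- floor(length(series$values) / n_per)
  if (n_win < 1) stop_invalid("series shorter than one step")
  v <- series$values[seq_len(n_win * n_per)]
  m <- matrix(v, nrow = n_per)
  out <- if (reducer == "rms") sqrt(colMeans(m^2)) else colMeans(m)
  sensor_series(out, dt = step, origin_time = series$origin_time,
                units = series$units)
}

#' Read an accelerometer CSV (`t, ax, ay, az`)
#'
#' @param path CSV path.
#' @return list with `xyz` matrix and `fs` inferred from the time column.
#' @export
read_accel_csv <- function(path) {
  df <- read.csv(path)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop_invalid("accelerometer CSV needs columns t, ax, ay, az")
  dt <- median(diff(df$t))
  list(xyz = as.matrix(df[, c("ax", "ay", "az")]), fs = 1 / dt)
}
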