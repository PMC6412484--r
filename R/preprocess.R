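#' Preprocessing configuration
#'
#' Parameters of the conventional sEMG conditioning chain and of the
#' gyroscope smoothing used by the detector.
#'
#' @param hp_cutoff_hz High-pass cut-off for the raw sEMG (Hz, default 3):
#'   removes hum noise and motion artifacts before rectification.
#' @param lp_envelope_hz Low-pass cut-off of the envelope smoother (Hz,
#'   default 10).
#' @param gyro_ma_window_s Width of the centered moving average applied to
#'   the gyro trace (seconds, default 0.1).
#' @param gyro_view_lp_hz Low-pass cut-off of the gait inspection view (Hz,
#'   default 3), highlighting the 0-3 Hz regular-gait content.
#' @param filter_order Order of the recursive (Butterworth) filters
#'   (default 4).
#' @param mode `"offline"` applies all recursive filters zero-phase
#'   (forward-backward), keeping envelope maxima aligned with gyro events;
#'   `"streaming"` uses the causal single-pass equivalents.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(hp_cutoff_hz = 3, lp_envelope_hz = 10,
                              gyro_ma_window_s = 0.1, gyro_view_lp_hz = 3,
                              filter_order = 4L,
                              mode = c("offline", "streaming")) {
  mode <- match.arg(mode)
  if (!(hp_cutoff_hz > 0 && hp_cutoff_hz < lp_envelope_hz))
    stop("preprocess_config: need 0 < hp_cutoff_hz < lp_envelope_hz",
         call. = FALSE)
  if (gyro_ma_window_s <= 0)
    stop("preprocess_config: gyro_ma_window_s must be > 0", call. = FALSE)
  if (filter_order < 1)
    stop("preprocess_config: filter_order must be >= 1", call. = FALSE)
  structure(list(hp_cutoff_hz = hp_cutoff_hz,
                 lp_envelope_hz = lp_envelope_hz,
                 gyro_ma_window_s = gyro_ma_window_s,
                 gyro_view_lp_hz = gyro_view_lp_hz,
                 filter_order = as.integer(filter_order), mode = mode),
            class = "preprocess_config")
}

# Butterworth filtering helper; zero-phase in offline mode, causal
# otherwise. Zero-phase filtering pads the trace by odd reflection (up to
# one second per side) so start-up transients decay inside the pads rather
# than contaminating the retained samples.
.butter_apply <- function(x, fs, cutoff_hz, type, order, mode) {
  if (any(cutoff_hz >= fs / 2))
    stop("filter cutoff must be below the Nyquist frequency (fs/2)",
         call. = FALSE)
  filt <- signal::butter(order, cutoff_hz / (fs / 2), type = type)
  if (mode == "offline") {
    n <- length(x)
    p <- min(n - 1L, as.integer(round(fs)))
    if (p > 0L) {
      xp <- c(2 * x[1] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
      y <- as.numeric(signal::filtfilt(filt, xp))
      y[(p + 1L):(p + n)]
    } else {
      as.numeric(signal::filtfilt(filt, x))
    }
  } else {
    as.numeric(signal::filter(filt, x))
  }
}

#' Linear envelope of a raw sEMG trace
#'
#' Conventional sEMG conditioning: high-pass filter (3 Hz) to reject hum and
#' motion artifacts, full-wave rectification (absolute value), normalization
#' to the maximum of the rectified signal, and low-pass smoothing (10 Hz).
#' The result quantifies the *intensity* of muscle activity on a `[0, 1]`
#' scale; small negative excursions caused by filter ringing are clipped at
#' zero (and overshoot above one at one) so downstream ratios always see a
#' nonnegative bounded envelope.
#'
#' @param raw A [signal_trace()] with `channel = "semg_raw"`.
#' @param cfg A [preprocess_config()].
#' @return A [signal_trace()] with `channel = "semg_envelope"`, same length,
#'   rate and grid as the input.
#' @export
semg_envelope <- function(raw, cfg = preprocess_config()) {
  stopifnot(inherits(raw, "signal_trace"))
  if (raw$channel != "semg_raw")
    stop("semg_envelope: input channel must be semg_raw", call. = FALSE)
  if (raw$fs <= 2 * cfg$lp_envelope_hz)
    stop("semg_envelope: fs must exceed twice the envelope cutoff",
         call. = FALSE)
  x <- raw$values
  scale_in <- max(abs(x))
  if (scale_in == 0)
    stop("semg_envelope: all-zero raw signal, normalization undefined",
         call. = FALSE)
  hp <- .butter_apply(x, raw$fs, cfg$hp_cutoff_hz, "high",
                      cfg$filter_order, cfg$mode)
  r <- abs(hp)
  m <- max(r)
  if (m < 1e-3 * scale_in) {
    # input had no content above the high-pass cutoff (e.g. pure DC);
    # what remains is the filter's numerical transient, so normalizing it
    # would amplify garbage and the envelope is zero instead
    env <- rep(0, length(x))
  } else {
    env <- .butter_apply(r / m, raw$fs, cfg$lp_envelope_hz, "low",
                         cfg$filter_order, cfg$mode)
    env <- pmin(pmax(env, 0), 1)
  }
  signal_trace(env, raw$fs, channel = "semg_envelope", side = raw$side,
               muscle = raw$muscle, units = "normalized", t0 = raw$t0)
}

#' Moving-average smoothing of the gyro trace
#'
#' Smooths the z-axis angular velocity with a centered moving average of
#' width `round(gyro_ma_window_s * fs)` samples (edges shrink to the valid
#' range) and divides by the session's gyro normalization constant, yielding
#' the smoothed normalized trace the detector thresholds operate on.
#'
#' @param gyro A [signal_trace()] with `channel = "gyro_z"`.
#' @param cfg A [preprocess_config()].
#' @param norm_const Normalization constant in the input units. `NULL`
#'   (default) uses the observed `max(abs(smoothed))`; a session-level
#'   full-scale reference may be passed instead (e.g. from a calibration
#'   prefix, or the synthetic generator's emitted full scale) so that
#'   low-activity recordings keep a meaningful threshold scale.
#' @return A [signal_trace()] on the same grid with normalized values; the
#'   constant used is stored in `$norm_const`.
#' @export
gyro_smooth <- function(gyro, cfg = preprocess_config(), norm_const = NULL) {
  stopifnot(inherits(gyro, "signal_trace"))
  if (gyro$channel != "gyro_z")
    stop("gyro_smooth: input channel must be gyro_z", call. = FALSE)
  x <- gyro$values
  n <- length(x)
  w <- max(1L, as.integer(round(cfg$gyro_ma_window_s * gyro$fs)))
  if (w > n)
    stop("gyro_smooth: moving-average window longer than the trace",
         call. = FALSE)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (is.null(norm_const)) norm_const <- max(abs(sm))
  if (!is.numeric(norm_const) || norm_const <= 0)
    stop("gyro_smooth: normalization constant must be positive ",
         "(all-zero gyro traces are rejected)", call. = FALSE)
  v <- sm / norm_const
  out <- signal_trace(v, gyro$fs, channel = "gyro_z", side = gyro$side,
                      muscle = gyro$muscle, units = "normalized",
                      t0 = gyro$t0,
                      normalized = abs(max(abs(v)) - 1) < 1e-12)
  out$norm_const <- norm_const
  out
}

#' Low-pass inspection view of the gyro trace
#'
#' Zero-phase low-pass filter at 3 Hz highlighting the regular-gait
#' frequency content (0-3 Hz). This is a display/inspection trace; the
#' detector operates on [gyro_smooth()] output instead.
#'
#' @param gyro A [signal_trace()] with `channel = "gyro_z"`.
#' @param cfg A [preprocess_config()].
#' @return A filtered [signal_trace()] on the same grid and scale.
#' @export
gyro_gait_view <- function(gyro, cfg = preprocess_config()) {
  stopifnot(inherits(gyro, "signal_trace"))
  if (gyro$channel != "gyro_z")
    stop("gyro_gait_view: input channel must be gyro_z", call. = FALSE)
  if (gyro$fs <= 2 * cfg$gyro_view_lp_hz)
    stop("gyro_gait_view: fs must exceed twice the view cutoff",
         call. = FALSE)
  v <- .butter_apply(gyro$values, gyro$fs, cfg$gyro_view_lp_hz, "low",
                     cfg$filter_order, "offline")
  out <- gyro
  out$values <- v
  out$normalized <- FALSE
  out
}
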