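#' @name synthgen
#' @title Synthetic bilateral gait and sEMG generation
#' @description Script-driven generator of bilateral gyro + sEMG sessions
#' reproducing the signal morphology of regular gait, shuffling-forward
#' FOG, trembling-in-place FOG and rest, with exact ground-truth interval
#' annotations. Waveforms are templates (raised-cosine gyro lobes,
#' amplitude-modulated band-limited noise carriers for the raw sEMG plus an
#' additive low-frequency activity-type component); they encode the
#' morphology the algorithms consume, not any real patient's numbers.
NULL

.synth_defaults <- list(
  regular_gait = list(
    cycle_s = 1.2,            # gait-cycle duration
    swing_amp_dps = 300,      # positive swing-lobe peak, degrees/s
    stance_depth_frac = 0.7,  # stance-lobe depth as fraction of swing amp
    swing_center = 0.25, swing_width = 0.29,    # fractions of the cycle
    stance_center = 0.71, stance_width = 0.33,
    ta_burst_mV = 1.0,        # biphasic TA swing bursts (early/late swing)
    ta_stance_mV = 0.25,      # mild TA activity near the stance ABS peak
    gc_burst_mV = 0.8,        # GC toe-off burst
    type_mV = 0.6,            # low-frequency activity-type amplitude
    burst_sigma = 0.03),      # burst width (fraction of the cycle)
  shuffling_fog = list(
    period_s = 0.55,          # one shuffle per period
    lobe_depth_dps = 45,      # shallow single negative gyro lobe
    lobe_width_frac = 0.55,   # lobe width as fraction of the period
    burst_mV = 0.6,           # single sEMG burst peaking at the gyro minimum
    burst_sigma_s = 0.12,
    baseline_mV = 0.05,
    antiphase = TRUE,         # left/right shuffles half a period apart
    ta_type_mV = 0.3,         # positive-oscillating TA type component
    gc_type_mV = -0.15,       # mildly stretched GC
    gc_burst_mV = 0.1),
  trembling_fog = list(
    band_hz = c(3, 8),        # knee-trembling gyro band
    gyro_rms_dps = 8,         # aperiodic, low-amplitude, zero-mean
    ta_burst_mV = 0.35,
    ta_mod_hz = 1.5,          # TA alternation rate
    ta_type_mV = 0.5,         # alternating-sign TA type component
    gc_type_mV = -0.25,       # tonically stretched GC
    gc_burst_mV = 0.05),      # very low GC intensity (toe-off deficit)
  rest = list())

.synth_ranges <- list(
  regular_gait = list(cycle_s = c(0.6, 2.5), swing_amp_dps = c(50, 1000),
                      stance_depth_frac = c(0.5, 0.95),
                      ta_burst_mV = c(0.1, 5), gc_burst_mV = c(0.05, 5),
                      type_mV = c(0.05, 5)),
  shuffling_fog = list(period_s = c(0.3, 1.0), lobe_depth_dps = c(10, 110),
                       burst_mV = c(0.05, 5), ta_type_mV = c(0.02, 5)),
  trembling_fog = list(gyro_rms_dps = c(2, 25), ta_burst_mV = c(0.05, 5),
                       ta_mod_hz = c(0.75, 4), gc_type_mV = c(-5, -0.02)),
  rest = list())

#' One segment of a synthetic gait script
#'
#' @param kind Segment kind: `"rest"`, `"regular_gait"`, `"shuffling_fog"`
#'   or `"trembling_fog"`.
#' @param duration_s Segment duration in seconds (> 0).
#' @param params Named list overriding the kind's default parameters (see
#'   the package defaults; amplitudes in degrees/s or millivolts). Values
#'   outside the documented ranges raise a validation error.
#' @return A list of class `segment_spec`.
#' @export
segment_spec <- function(kind = c("rest", "regular_gait", "shuffling_fog",
                                  "trembling_fog"),
                         duration_s, params = list()) {
  kind <- match.arg(kind)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("segment_spec: duration_s must be > 0", call. = FALSE)
  defaults <- .synth_defaults[[kind]]
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("segment_spec: unknown parameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  p <- utils::modifyList(defaults, params)
  rng <- .synth_ranges[[kind]]
  for (nm in names(rng)) {
    if (p[[nm]] < rng[[nm]][1] || p[[nm]] > rng[[nm]][2])
      stop(sprintf("segment_spec: %s = %g outside documented range [%g, %g]",
                   nm, p[[nm]], rng[[nm]][1], rng[[nm]][2]), call. = FALSE)
  }
  structure(list(kind = kind, duration_s = duration_s, params = p),
            class = "segment_spec")
}

#' Ordered synthetic recording plan
#'
#' @param segments List of [segment_spec()] objects (total duration > 0).
#' @param fs Sampling rate in Hz (default 200, >= 50).
#' @param seed Integer seed making the generated session deterministic.
#' @param full_scale_dps Gyro full-scale reference used for normalization,
#'   emulating the subject's regular swing amplitude. `NULL` (default)
#'   takes the largest `swing_amp_dps` among regular segments, falling back
#'   to 300 when the script has none, so that rest-only scripts remain
#'   processable.
#' @return A list of class `gait_script`.
#' @export
gait_script <- function(segments, fs = 200, seed = 1L,
                        full_scale_dps = NULL) {
  if (!length(segments) ||
      !all(vapply(segments, inherits, logical(1), "segment_spec")))
    stop("gait_script: 'segments' must be a list of segment_spec objects",
         call. = FALSE)
  if (fs < 50)
    stop("gait_script: fs must be >= 50 Hz", call. = FALSE)
  if (is.null(full_scale_dps)) {
    amps <- vapply(segments, function(s)
      if (s$kind == "regular_gait") s$params$swing_amp_dps else NA_real_,
      numeric(1))
    full_scale_dps <- if (all(is.na(amps))) 300 else max(amps, na.rm = TRUE)
  }
  structure(list(segments = segments, fs = fs, seed = as.integer(seed),
                 full_scale_dps = full_scale_dps),
            class = "gait_script")
}

# circular raised-cosine lobe and gaussian bump on a cyclic phase grid
.rc_circ <- function(u, center, width, period) {
  d <- abs(u - center)
  d <- pmin(d, period - d)
  ifelse(d < width / 2, 0.5 * (1 + cos(2 * pi * d / width)), 0)
}

.gauss_circ <- function(u, center, sigma, period) {
  d <- abs(u - center)
  d <- pmin(d, period - d)
  exp(-d^2 / (2 * sigma^2))
}

.bandlimited_noise <- function(n, fs, band_hz) {
  hi <- min(band_hz[2], 0.45 * fs)
  lo <- min(band_hz[1], 0.8 * hi)
  filt <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(filt, stats::rnorm(n)))
  x / max(stats::sd(x), 1e-12)
}

# fill per-side component vectors for one segment; comp is an environment
# holding gyro, ta_b, ta_type, gc_b, gc_type
.fill_segment <- function(comp, i0, n, fs, seg, side) {
  if (n < 1L) return(invisible())
  idx <- i0:(i0 + n - 1L)
  t <- (0:(n - 1)) / fs
  p <- seg$params
  if (seg$kind == "regular_gait") {
    phase <- if (side == "left") p$cycle_s / 2 else 0
    u <- (t + phase) %% p$cycle_s
    C <- p$cycle_s
    comp$gyro[idx] <- comp$gyro[idx] +
      p$swing_amp_dps * .rc_circ(u, p$swing_center * C, p$swing_width * C, C) -
      p$swing_amp_dps * p$stance_depth_frac *
        .rc_circ(u, p$stance_center * C, p$stance_width * C, C)
    sg <- p$burst_sigma * C
    comp$ta_b[idx] <- comp$ta_b[idx] + 0.02 +
      p$ta_burst_mV * (.gauss_circ(u, 0.125 * C, sg, C) +
                       .gauss_circ(u, 0.375 * C, sg, C)) +
      p$ta_stance_mV * .gauss_circ(u, p$stance_center * C, 1.3 * sg, C)
    comp$gc_b[idx] <- comp$gc_b[idx] + 0.02 +
      p$gc_burst_mV * .gauss_circ(u, 0.08 * C, 1.3 * sg, C)
    comp$ta_type[idx] <- comp$ta_type[idx] +
      p$type_mV * (.rc_circ(u, p$swing_center * C, 0.35 * C, C) -
                   0.7 * .rc_circ(u, p$stance_center * C, 0.40 * C, C))
    comp$gc_type[idx] <- comp$gc_type[idx] +
      p$type_mV * (.rc_circ(u, 0.08 * C, 0.25 * C, C) -
                   0.5 * .rc_circ(u, p$swing_center * C, 0.35 * C, C))
  } else if (seg$kind == "shuffling_fog") {
    phase <- if (isTRUE(p$antiphase) && side == "left") p$period_s / 2 else 0
    u <- (t + phase) %% p$period_s
    P <- p$period_s
    lobe <- .rc_circ(u, P / 2, p$lobe_width_frac * P, P)
    comp$gyro[idx] <- comp$gyro[idx] - p$lobe_depth_dps * lobe
    comp$ta_b[idx] <- comp$ta_b[idx] + p$baseline_mV +
      p$burst_mV * .gauss_circ(u, P / 2, p$burst_sigma_s, P)
    comp$gc_b[idx] <- comp$gc_b[idx] + p$gc_burst_mV
    comp$ta_type[idx] <- comp$ta_type[idx] +
      p$ta_type_mV * (0.6 + 0.4 * sin(2 * pi * (t + phase) / P))
    comp$gc_type[idx] <- comp$gc_type[idx] + p$gc_type_mV
  } else if (seg$kind == "trembling_fog") {
    comp$gyro[idx] <- comp$gyro[idx] +
      p$gyro_rms_dps * .bandlimited_noise(n, fs, p$band_hz)
    phi <- stats::runif(1, 0, 2 * pi)
    comp$ta_b[idx] <- comp$ta_b[idx] +
      p$ta_burst_mV * (0.7 + 0.3 * sin(2 * pi * p$ta_mod_hz * t + phi))
    comp$gc_b[idx] <- comp$gc_b[idx] + p$gc_burst_mV
    comp$ta_type[idx] <- comp$ta_type[idx] +
      p$ta_type_mV * sin(2 * pi * p$ta_mod_hz * t + phi)
    comp$gc_type[idx] <- comp$gc_type[idx] + p$gc_type_mV
  }
  invisible()
}

#' Generate a synthetic bilateral recording session
#'
#' Builds, deterministically given the script seed, the eight traces of a
#' bilateral two-device recording (z-axis gyro and raw sEMG for TA and GC,
#' both sides) plus ground-truth annotations matching the segment
#' boundaries exactly. Raw sEMG is an amplitude-modulated 20-80 Hz
#' band-limited noise carrier (intensity) plus an additive low-frequency
#' signed component (activity type) and a sensor noise floor; the gyro is
#' built from raised-cosine swing/stance or shuffle lobes, band-limited
#' trembling noise, and a sensor noise floor.
#'
#' Per-kind signal contracts (at default amplitudes, after normalization by
#' the emitted full-scale reference): regular cycles give one positive
#' swing lobe and one stance lobe deeper than the stance threshold; shuffle
#' lobes stay shallow (about 0.15) with a single sEMG burst peaking at the
#' gyro minimum and left/right antiphase; trembling gyro is aperiodic
#' zero-mean noise of normalized amplitude below about 0.1 with alternating
#' TA and tonically stretched low-intensity GC; rest stays below the
#' window-opening threshold throughout.
#'
#' @param script A [gait_script()].
#' @param seed Overrides the script seed when given.
#' @return A [recording_session()]; `meta` records the seed, `fs` and
#'   `gyro_full_scale_dps` (the normalization reference).
#' @export
generate_session <- function(script, seed = NULL) {
  stopifnot(inherits(script, "gait_script"))
  if (is.null(seed)) seed <- script$seed
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  fs <- script$fs
  n_seg <- vapply(script$segments, function(s)
    as.integer(round(s$duration_s * fs)), integer(1))
  N <- sum(n_seg)
  if (N < 2L) stop("generate_session: script too short", call. = FALSE)
  bounds <- cumsum(c(0L, n_seg))

  gyro_noise_dps <- 0.5
  semg_noise_mV <- 0.01
  traces <- list()
  for (side in c("right", "left")) {
    comp <- new.env()
    comp$gyro <- numeric(N)
    comp$ta_b <- numeric(N); comp$ta_type <- numeric(N)
    comp$gc_b <- numeric(N); comp$gc_type <- numeric(N)
    for (j in seq_along(script$segments))
      .fill_segment(comp, bounds[j] + 1L, n_seg[j], fs,
                    script$segments[[j]], side)
    for (muscle in c("TA", "GC")) {
      g <- comp$gyro + stats::rnorm(N, 0, gyro_noise_dps)
      traces[[length(traces) + 1L]] <-
        signal_trace(g, fs, channel = "gyro_z", side = side,
                     muscle = muscle, units = "dps")
      carrier <- .bandlimited_noise(N, fs, c(20, 80))
      b <- if (muscle == "TA") comp$ta_b else comp$gc_b
      ty <- if (muscle == "TA") comp$ta_type else comp$gc_type
      raw <- b * carrier + ty + stats::rnorm(N, 0, semg_noise_mV)
      traces[[length(traces) + 1L]] <-
        signal_trace(raw, fs, channel = "semg_raw", side = side,
                     muscle = muscle, units = "mV")
    }
  }
  kinds <- vapply(script$segments, `[[`, character(1), "kind")
  ann <- annotation_set(start_s = bounds[-length(bounds)] / fs,
                        end_s = bounds[-1] / fs,
                        label = ifelse(kinds == "rest", "rest",
                                ifelse(kinds == "regular_gait",
                                       "regular_gait", kinds)))
  recording_session(traces, ann,
                    meta = list(seed = seed, fs = fs,
                                gyro_full_scale_dps = script$full_scale_dps))
}

#' Default timed-up-and-go-like script
#'
#' A roughly one-minute plan mirroring a sit-walk-freeze sequence: rest,
#' regular gait, a shuffling episode, rest, a second shuffling episode, a
#' trembling episode, regular gait, rest. Segment durations are exact
#' multiples of the cycle/shuffle periods so no lobe is clipped at a
#' boundary.
#'
#' @param seed Integer seed for the script.
#' @param fs Sampling rate in Hz.
#' @return A [gait_script()] of total duration within \[50, 70\] s
#'   containing at least one segment of every kind.
#' @export
default_tug_script <- function(seed = 1L, fs = 200) {
  gait_script(list(
    segment_spec("rest", 5),
    segment_spec("regular_gait", 12),        # 10 cycles
    segment_spec("shuffling_fog", 8.25),     # 15 shuffles
    segment_spec("rest", 4),
    segment_spec("shuffling_fog", 6.05),     # 11 shuffles
    segment_spec("trembling_fog", 8),
    segment_spec("regular_gait", 9.6),       # 8 cycles
    segment_spec("rest", 5)), fs = fs, seed = seed)
}
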