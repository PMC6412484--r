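#' Ensemble-averaging configuration
#'
#' @param segment_s Segment duration extracted after each anchor (seconds,
#'   default 1, the step-scale analysis interval).
#' @param resample_len Number of points each segment is time-normalized to
#'   (default 200, >= 10).
#' @param alignment Anchor definition used by callers: `"window_start"`
#'   (step-window starts from the detector) or `"gyro_peak"`.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(segment_s = 1.0, resample_len = 200L,
                            alignment = c("window_start", "gyro_peak")) {
  alignment <- match.arg(alignment)
  if (segment_s <= 0)
    stop("ensemble_config: segment_s must be > 0", call. = FALSE)
  resample_len <- as.integer(resample_len)
  if (resample_len < 10L)
    stop("ensemble_config: resample_len must be >= 10", call. = FALSE)
  structure(list(segment_s = segment_s, resample_len = resample_len,
                 alignment = alignment), class = "ensemble_config")
}

#' Decode muscle activity type (contraction vs stretching) and intensity
#'
#' The *type* of muscle activity is read from the low-frequency portion of
#' the raw sEMG signal: the raw trace (not high-pass filtered — the
#' low-frequency content is the signal here) is low-pass filtered below
#' `lp_hz`, normalized by its absolute maximum, and its sign decoded with a
#' small deadband: values above `+deadband` mean contraction, below
#' `-deadband` stretching, and in between quiescent. The *intensity* is the
#' conventional linear envelope of the same raw trace. The normalization
#' reference is floored at 20% of the raw-signal scale so recordings
#' without genuine low-frequency content decode as quiescent rather than
#' amplifying filter residue into spurious labels.
#'
#' @param raw A [signal_trace()] with `channel = "semg_raw"` and
#'   `fs > 20` Hz.
#' @param lp_hz Low-pass cut-off for the type trace (default 10 Hz).
#' @param deadband Half-width of the quiescent zone on the normalized type
#'   scale (default 0.05); a raw sign rule would be noise-fragile at zero
#'   crossings.
#' @param pre_cfg A [preprocess_config()] used for the intensity envelope
#'   and the filter family of the type low-pass.
#' @return A list of class `activity_trace` with `type_values` (signed,
#'   normalized), `intensity_values` (envelope in `[0, 1]`), per-sample
#'   `labels` in `{contraction, stretching, quiescent}`, plus `muscle`,
#'   `side`, `fs`, `t0` and the `deadband` used.
#' @export
activity_type <- function(raw, lp_hz = 10, deadband = 0.05,
                          pre_cfg = preprocess_config()) {
  stopifnot(inherits(raw, "signal_trace"))
  if (raw$channel != "semg_raw")
    stop("activity_type: input channel must be semg_raw", call. = FALSE)
  if (raw$fs <= 20)
    stop("activity_type: fs must exceed 20 Hz", call. = FALSE)
  if (max(abs(raw$values)) == 0)
    stop("activity_type: all-zero raw signal", call. = FALSE)
  lf <- .butter_apply(raw$values, raw$fs, lp_hz, "low",
                      pre_cfg$filter_order, pre_cfg$mode)
  # scale reference: the low-frequency maximum, but never below 20% of the
  # raw-signal scale, so a recording without genuine low-frequency content
  # decodes as quiescent instead of amplifying filter residue
  m <- max(max(abs(lf)), 0.2 * max(abs(raw$values)))
  type_values <- lf / m
  labels <- rep("quiescent", length(type_values))
  labels[type_values > deadband] <- "contraction"
  labels[type_values < -deadband] <- "stretching"
  env <- semg_envelope(raw, pre_cfg)
  structure(list(type_values = type_values,
                 intensity_values = env$values,
                 labels = labels, muscle = raw$muscle, side = raw$side,
                 fs = raw$fs, t0 = raw$t0, deadband = deadband),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  tab <- table(factor(x$labels,
                      levels = c("contraction", "stretching", "quiescent")))
  cat(sprintf(paste0("<activity_trace> %s/%s: %d samples @ %g Hz ",
                     "(%.0f%% contraction, %.0f%% stretching)\n"),
              x$side, x$muscle, length(x$type_values), x$fs,
              100 * tab[["contraction"]] / length(x$labels),
              100 * tab[["stretching"]] / length(x$labels)))
  invisible(x)
}

#' Extract step-aligned, time-normalized segments of an activity trace
#'
#' For each anchor time, the segment `[anchor, anchor + segment_s)` is
#' extracted and linearly resampled to `resample_len` points (time
#' normalization). Anchors too close to the trace end for a full segment
#' are skipped and counted.
#'
#' @param activity An [activity_type()] result.
#' @param anchors_s Numeric vector of anchor times in seconds (typically
#'   step-window starts).
#' @param cfg An [ensemble_config()].
#' @param field Which trace to segment: `"type"` (default) or
#'   `"intensity"`.
#' @return A list with `segments` (matrix `resample_len x n_kept`, one
#'   column per segment) and `skipped` (number of anchors dropped).
#' @export
extract_step_segments <- function(activity, anchors_s,
                                  cfg = ensemble_config(),
                                  field = c("type", "intensity")) {
  field <- match.arg(field)
  v <- if (field == "type") activity$type_values else
    activity$intensity_values
  n <- length(v)
  t_end <- activity$t0 + (n - 1) / activity$fs
  t_in <- activity$t0 + (seq_len(n) - 1) / activity$fs
  L <- cfg$resample_len
  keep <- !is.na(anchors_s) & anchors_s >= activity$t0 &
    (anchors_s + cfg$segment_s) <= t_end + 1e-9
  skipped <- sum(!keep)
  anchors <- anchors_s[keep]
  segs <- matrix(numeric(0), nrow = L, ncol = 0)
  if (length(anchors)) {
    segs <- vapply(anchors, function(a) {
      t_out <- a + (0:(L - 1)) / L * cfg$segment_s
      stats::approx(t_in, v, xout = t_out, rule = 2)$y
    }, numeric(L))
    segs <- matrix(segs, nrow = L)
  }
  list(segments = segs, skipped = skipped)
}

#' Pointwise ensemble mean and standard deviation of step segments
#'
#' @param segments Matrix with one equal-length segment per column (at
#'   least one column).
#' @return A list with `mean` and `sd`, each of the segment length (`sd` is
#'   zero when only one segment is supplied), and `n` segments.
#' @export
ensemble_average <- function(segments) {
  segments <- as.matrix(segments)
  k <- ncol(segments)
  if (k < 1L)
    stop("ensemble_average: need at least one segment", call. = FALSE)
  m <- rowMeans(segments)
  s <- if (k == 1L) rep(0, nrow(segments)) else
    sqrt(rowSums((segments - m)^2) / (k - 1))
  list(mean = m, sd = s, n = k)
}

#' Gastrocnemius deficit summary per annotation label
#'
#' For each annotation label, the fraction of GC samples decoded as
#' stretching and the mean envelope intensity. During trembling-in-place
#' FOG the GC typically remains stretched at very low intensity (toe-off
#' deficit); this summary lets that pattern be quantified per condition.
#' Labels with zero samples inside the trace are omitted.
#'
#' @param gc_activity An [activity_type()] result (typically the GC).
#' @param annotations An [annotation_set()].
#' @return A data frame with `label`, `n_samples`, `fraction_stretching`,
#'   `mean_intensity`.
#' @export
gc_deficit_summary <- function(gc_activity, annotations) {
  validate_annotations(annotations)
  n <- length(gc_activity$type_values)
  t <- gc_activity$t0 + (seq_len(n) - 1) / gc_activity$fs
  lab_at <- annotation_label_at(annotations, t)
  out <- lapply(unique(annotations$label), function(lbl) {
    sel <- !is.na(lab_at) & lab_at == lbl
    if (!any(sel)) return(NULL)
    data.frame(label = lbl, n_samples = sum(sel),
               fraction_stretching =
                 mean(gc_activity$labels[sel] == "stretching"),
               mean_intensity = mean(gc_activity$intensity_values[sel]))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
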