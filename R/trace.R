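#' One uniformly sampled sensor channel
#'
#' A `signal_trace` holds a single uniformly sampled channel recorded by a
#' shank-worn device: z-axis angular velocity (`gyro_z`, degrees/s), raw
#' surface EMG (`semg_raw`, volts or millivolts), a processed sEMG envelope
#' (`semg_envelope`, normalized to `[0, 1]`), a low-frequency sEMG "type"
#' trace (`semg_type`), or a derived fused trace (`fused`). Samples lie on
#' the uniform grid `t0 + (i - 1) / fs`.
#'
#' @param values Numeric vector of samples (length >= 1, no missing values).
#' @param fs Sampling rate in Hz (single positive number).
#' @param channel Channel kind, one of `"gyro_z"`, `"semg_raw"`,
#'   `"semg_envelope"`, `"semg_type"`, `"fused"`.
#' @param side Body side the device was worn on, `"right"` or `"left"`.
#' @param muscle Muscle the device sits over: `"TA"` (tibialis anterior),
#'   `"GC"` (gastrocnemius) or `"none"`.
#' @param units Free-form unit string (e.g. `"dps"`, `"mV"`).
#' @param t0 Time of the first sample in seconds.
#' @param normalized Logical; `TRUE` only when `max(abs(values)) == 1`
#'   exactly (all-zero traces can never be flagged normalized).
#' @return An object of class `signal_trace`.
#' @seealso [normalize_abs_max()], [recording_session()]
#' @export
signal_trace <- function(values, fs,
                         channel = c("gyro_z", "semg_raw", "semg_envelope",
                                     "semg_type", "fused"),
                         side = c("right", "left"),
                         muscle = c("none", "TA", "GC"),
                         units = "", t0 = 0, normalized = FALSE) {
  channel <- match.arg(channel)
  side <- match.arg(side)
  muscle <- match.arg(muscle)
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("signal_trace: 'values' must have length >= 1", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("signal_trace: samples must be finite (uniform grid, no gaps)",
         call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("signal_trace: 'fs' must be a single positive number", call. = FALSE)
  if (channel == "semg_envelope" &&
      (min(values) < 0 || max(values) > 1 + 1e-12))
    stop("signal_trace: envelope values must lie in [0, 1]", call. = FALSE)
  if (isTRUE(normalized)) {
    m <- max(abs(values))
    if (m == 0)
      stop("signal_trace: an all-zero trace cannot be flagged normalized",
           call. = FALSE)
    if (abs(m - 1) > 1e-12)
      stop("signal_trace: normalized trace must have max(|values|) == 1",
           call. = FALSE)
  }
  structure(
    list(values = values, fs = fs, channel = channel, side = side,
         muscle = muscle, units = units, t0 = t0,
         normalized = isTRUE(normalized)),
    class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s %s/%s: %d samples @ %g Hz, t0 = %g s%s\n",
              x$channel, x$side, x$muscle, length(x$values), x$fs, x$t0,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A [signal_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) / trace$fs
}

#' Duration of a trace in seconds
#' @param trace A [signal_trace()].
#' @return Duration `length(values) / fs` in seconds.
#' @export
trace_duration <- function(trace) length(trace$values) / trace$fs

#' Nearest sample index for a time point
#' @param trace A [signal_trace()].
#' @param t Time in seconds.
#' @return 1-based sample index (may fall outside the trace; check bounds).
#' @export
time_to_index <- function(trace, t) {
  as.integer(round((t - trace$t0) * trace$fs)) + 1L
}

#' Extract the sub-trace covering a half-open time interval
#'
#' @param trace A [signal_trace()].
#' @param start_s,end_s Interval bounds in seconds, `[start_s, end_s)`.
#' @return A [signal_trace()] with `t0 = ` time of its first sample. The
#'   `normalized` flag is dropped (a slice of a normalized trace need not
#'   attain 1).
#' @export
slice_trace <- function(trace, start_s, end_s) {
  if (end_s <= start_s) stop("slice_trace: end_s must exceed start_s",
                             call. = FALSE)
  i0 <- max(1L, time_to_index(trace, start_s))
  i1 <- min(length(trace$values),
            as.integer(ceiling((end_s - trace$t0) * trace$fs)))
  if (i1 < i0) stop("slice_trace: interval outside trace domain",
                    call. = FALSE)
  out <- trace
  out$values <- trace$values[i0:i1]
  out$t0 <- trace$t0 + (i0 - 1) / trace$fs
  out$normalized <- FALSE
  out
}

#' Rescale a trace so that its absolute maximum equals one
#'
#' All traces entering the detection and phenotype stages are normalized
#' with respect to their absolute maximum so that recordings from different
#' subjects and gains become comparable. The sign pattern is preserved and
#' the scaling constant is retained in `$norm_const` so the original scale
#' can be recovered.
#'
#' @param trace A [signal_trace()] with `max(abs(values)) > 0`.
#' @return The trace with `values / max(abs(values))`, `normalized = TRUE`
#'   and the divisor stored in `$norm_const`.
#' @export
normalize_abs_max <- function(trace) {
  stopifnot(inherits(trace, "signal_trace"))
  m <- max(abs(trace$values))
  if (m == 0)
    stop("normalize_abs_max: all-zero trace, normalization undefined",
         call. = FALSE)
  trace$values <- trace$values / m
  trace$normalized <- TRUE
  trace$norm_const <- m
  trace
}

trace_key <- function(side, muscle, channel) {
  paste(side, muscle, channel, sep = "_")
}

#' Bilateral multi-muscle recording session
#'
#' A `recording_session` bundles all channels recorded in one test (both
#' legs, TA and/or GC devices) together with interval annotations and
#' free-form metadata. All traces must share the sampling rate and length;
#' resampling, when needed, happens at load time (see [read_trace_file()]).
#'
#' @param traces List of [signal_trace()] objects. Keys are derived as
#'   `side_muscle_channel`; at most one trace per key.
#' @param annotations An [annotation_set()] (may be empty).
#' @param meta Named list of free-form metadata (subject id, seed,
#'   `gyro_full_scale_dps`, ...).
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(traces = list(), annotations = annotation_set(),
                              meta = list()) {
  keys <- vapply(traces, function(tr)
    trace_key(tr$side, tr$muscle, tr$channel), character(1))
  if (anyDuplicated(keys))
    stop("recording_session: duplicate (side, muscle, channel) key: ",
         keys[duplicated(keys)][1], call. = FALSE)
  names(traces) <- keys
  if (length(traces) > 1L) {
    fss <- vapply(traces, `[[`, numeric(1), "fs")
    lens <- vapply(traces, function(tr) length(tr$values), integer(1))
    if (length(unique(fss)) != 1L || length(unique(lens)) != 1L)
      stop("recording_session: all traces must share fs and length",
           call. = FALSE)
  }
  validate_annotations(annotations)
  structure(list(traces = traces, annotations = annotations, meta = meta),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %d trace(s), %d annotation(s)\n",
              length(x$traces), nrow(x$annotations)))
  for (k in names(x$traces)) cat("  ", k, "\n", sep = "")
  invisible(x)
}

#' Retrieve one trace from a session
#'
#' @param session A [recording_session()].
#' @param side,muscle,channel Key components.
#' @return The matching [signal_trace()]; error if absent.
#' @export
get_trace <- function(session, side, muscle, channel) {
  key <- trace_key(side, muscle, channel)
  tr <- session$traces[[key]]
  if (is.null(tr))
    stop("get_trace: no trace for key '", key, "'", call. = FALSE)
  tr
}

#' Add or replace a trace in a session
#' @param session A [recording_session()].
#' @param trace A [signal_trace()].
#' @return The updated session.
#' @export
put_trace <- function(session, trace) {
  traces <- session$traces
  traces[[trace_key(trace$side, trace$muscle, trace$channel)]] <- trace
  recording_session(traces, session$annotations, session$meta)
}

.annotation_labels <- c("regular_gait", "shuffling_fog", "trembling_fog",
                        "rest", "turning")

#' Interval annotations for a recording
#'
#' Ground-truth (or clinician-reference) labelling of a recording as a set
#' of non-overlapping, time-ordered intervals. Labels come from the closed
#' vocabulary `regular_gait`, `shuffling_fog`, `trembling_fog`, `rest`,
#' `turning`.
#'
#' @param start_s,end_s Numeric vectors of interval bounds in seconds
#'   (`start_s < end_s` elementwise).
#' @param label Character vector of labels.
#' @return A data frame of class `annotation_set` with columns `start_s`,
#'   `end_s`, `label`, sorted by `start_s`.
#' @export
annotation_set <- function(start_s = numeric(0), end_s = numeric(0),
                           label = character(0)) {
  ann <- data.frame(start_s = as.numeric(start_s),
                    end_s = as.numeric(end_s),
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$start_s), , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("annotation_set", "data.frame")
  validate_annotations(ann)
  ann
}

#' Validate an annotation set
#'
#' Checks the closed label vocabulary, `start_s < end_s`, ordering by
#' `start_s`, and that no two intervals overlap.
#'
#' @param ann An [annotation_set()] (or bare data frame with its columns).
#' @return The validated annotation set, invisibly; error otherwise.
#' @export
validate_annotations <- function(ann) {
  if (!all(c("start_s", "end_s", "label") %in% names(ann)))
    stop("annotations need columns start_s, end_s, label", call. = FALSE)
  if (nrow(ann) == 0L) return(invisible(ann))
  bad <- setdiff(unique(ann$label), .annotation_labels)
  if (length(bad))
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(ann$start_s >= ann$end_s))
    stop("annotations must satisfy start_s < end_s", call. = FALSE)
  if (is.unsorted(ann$start_s))
    stop("annotations must be sorted by start_s", call. = FALSE)
  if (nrow(ann) > 1L &&
      any(ann$start_s[-1] < ann$end_s[-nrow(ann)] - 1e-9))
    stop("annotation intervals must not overlap", call. = FALSE)
  invisible(ann)
}

#' Label of the annotation interval containing given time points
#'
#' @param ann An [annotation_set()].
#' @param t Numeric vector of times in seconds.
#' @return Character vector: the label of the interval with
#'   `start_s <= t < end_s`, or `NA` where no interval contains `t`.
#' @export
annotation_label_at <- function(ann, t) {
  out <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(ann))) {
    hit <- t >= ann$start_s[i] & t < ann$end_s[i]
    out[hit] <- ann$label[i]
  }
  out
}
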