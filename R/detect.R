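#' Detector configuration
#'
#' Thresholds and bookkeeping parameters of the step-window FOG detector.
#' `T1` and `T2` act on the normalized smoothed gyro scale and are constant
#' across subjects.
#'
#' @param T1 Supra-threshold level on `|gyro_smoothed|` that opens/closes a
#'   step window (default 0.01).
#' @param T2 Negative stance-rejection threshold on the smoothed gyro
#'   (default -0.4): windows whose minimum goes at or below `T2` are the
#'   deep stance lobes of regular steps and are skipped (no R computed).
#' @param R_demarcation Demarcation level for the R index (default 3);
#'   `R >= R_demarcation` classifies a step as regular, below as FOG.
#' @param min_win_s Minimum window duration in seconds (default 0.05);
#'   shorter windows are threshold chatter and are discarded.
#' @param envelope_floor Lower bound on the envelope denominator of R
#'   (default 1e-6) guarding against division by zero.
#' @param episode_gap_s Maximum gap between consecutive FOG windows merged
#'   into one episode (default 1 s).
#' @param min_episode_windows Minimum number of FOG windows forming an
#'   episode (default 2).
#' @return A list of class `detector_config`.
#' @export
detector_config <- function(T1 = 0.01, T2 = -0.4, R_demarcation = 3,
                            min_win_s = 0.05, envelope_floor = 1e-6,
                            episode_gap_s = 1.0,
                            min_episode_windows = 2L) {
  if (!(T1 > 0 && T1 < 1))
    stop("detector_config: need 0 < T1 < 1", call. = FALSE)
  if (!(T2 > -1 && T2 < 0))
    stop("detector_config: need -1 < T2 < 0", call. = FALSE)
  if (R_demarcation <= 0)
    stop("detector_config: R_demarcation must be > 0", call. = FALSE)
  if (envelope_floor <= 0)
    stop("detector_config: envelope_floor must be > 0", call. = FALSE)
  if (min_win_s < 0 || episode_gap_s < 0)
    stop("detector_config: durations must be nonnegative", call. = FALSE)
  structure(list(T1 = T1, T2 = T2, R_demarcation = R_demarcation,
                 min_win_s = min_win_s, envelope_floor = envelope_floor,
                 episode_gap_s = episode_gap_s,
                 min_episode_windows = as.integer(min_episode_windows)),
            class = "detector_config")
}

#' Absolute value of the smoothed normalized gyro trace
#'
#' @param gyro_smoothed Output of [gyro_smooth()].
#' @return A [signal_trace()] with pointwise `abs(values)`.
#' @export
abs_trace <- function(gyro_smoothed) {
  stopifnot(inherits(gyro_smoothed, "signal_trace"))
  out <- gyro_smoothed
  out$values <- abs(gyro_smoothed$values)
  out$normalized <- FALSE
  out
}

.windows_df <- function(start_idx, end_idx, abs_values, gyro_values, fs, t0) {
  k <- length(start_idx)
  max_abs <- numeric(k); i_max <- integer(k); min_gyro <- numeric(k)
  for (j in seq_len(k)) {
    seg <- abs_values[start_idx[j]:(end_idx[j] - 1L)]
    jm <- which.max(seg)
    max_abs[j] <- seg[jm]
    i_max[j] <- start_idx[j] + jm - 1L
    min_gyro[j] <- min(gyro_values[start_idx[j]:(end_idx[j] - 1L)])
  }
  df <- data.frame(start_idx = start_idx, end_idx = end_idx,
                   start_s = t0 + (start_idx - 1) / fs,
                   end_s = t0 + (end_idx - 1) / fs,
                   i_max_abs = i_max,
                   t_max_abs = t0 + (i_max - 1) / fs,
                   max_abs = max_abs, min_gyro = min_gyro)
  class(df) <- c("step_windows", "data.frame")
  df
}

#' Segment the recording into step windows
#'
#' A step (or step attempt) window opens at the first sample where the
#' absolute smoothed gyro `ABS` passes from at-or-below to above `T1`, and
#' closes at the next sample where it returns to at-or-below `T1`
#' (half-open `[start_idx, end_idx)`). When `ABS` never exceeds `T1` the
#' subject is resting and no window is defined. Windows shorter than
#' `min_win_s` are discarded; a final unterminated window is dropped in
#' offline mode (the streaming interface reports it as open instead, see
#' [detect_step_windows_stream()]).
#'
#' @param abs_tr Output of [abs_trace()].
#' @param gyro_smoothed Output of [gyro_smooth()], same grid.
#' @param cfg A [detector_config()].
#' @return A data frame of class `step_windows` with one row per window:
#'   `start_idx`, `end_idx`, `start_s`, `end_s`, `i_max_abs`, `t_max_abs`,
#'   `max_abs`, `min_gyro`.
#' @export
detect_step_windows <- function(abs_tr, gyro_smoothed,
                                cfg = detector_config()) {
  stopifnot(inherits(abs_tr, "signal_trace"),
            inherits(gyro_smoothed, "signal_trace"))
  if (length(abs_tr$values) != length(gyro_smoothed$values) ||
      abs_tr$fs != gyro_smoothed$fs)
    stop("detect_step_windows: traces must share the sample grid",
         call. = FALSE)
  a <- abs_tr$values
  n <- length(a)
  above <- a > cfg$T1
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L)
  if (length(starts) && ends[length(ends)] == n + 1L) {
    # unterminated final window: dropped offline
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  keep <- (ends - starts) / abs_tr$fs >= cfg$min_win_s
  starts <- starts[keep]; ends <- ends[keep]
  .windows_df(starts, ends, a, gyro_smoothed$values, abs_tr$fs, abs_tr$t0)
}

#' Chunked (streaming) step-window segmentation
#'
#' Processes the trace in consecutive chunks while carrying the open-window
#' state across chunk boundaries, as an on-device implementation would.
#' Closed windows are identical to [detect_step_windows()] output on the
#' same normalized input; a window still open when the stream ends is
#' reported with `open = TRUE` instead of being dropped.
#'
#' @inheritParams detect_step_windows
#' @param chunk_s Chunk duration in seconds (default 0.5).
#' @return A `step_windows` data frame with an extra logical column `open`.
#' @export
detect_step_windows_stream <- function(abs_tr, gyro_smoothed,
                                       cfg = detector_config(),
                                       chunk_s = 0.5) {
  a <- abs_tr$values
  n <- length(a)
  chunk <- max(1L, as.integer(round(chunk_s * abs_tr$fs)))
  starts <- integer(0); ends <- integer(0)
  in_win <- FALSE; cur_start <- NA_integer_
  pos <- 1L
  while (pos <= n) {
    hi <- min(n, pos + chunk - 1L)
    for (i in pos:hi) {
      if (!in_win && a[i] > cfg$T1) {
        in_win <- TRUE; cur_start <- i
      } else if (in_win && a[i] <= cfg$T1) {
        starts <- c(starts, cur_start); ends <- c(ends, i)
        in_win <- FALSE
      }
    }
    pos <- hi + 1L
  }
  open_flag <- logical(length(starts))
  if (in_win) {
    starts <- c(starts, cur_start); ends <- c(ends, n + 1L)
    open_flag <- c(open_flag, TRUE)
  }
  keep <- (ends - starts) / abs_tr$fs >= cfg$min_win_s
  starts <- starts[keep]; ends <- ends[keep]; open_flag <- open_flag[keep]
  df <- .windows_df(starts, pmin(ends, n + 1L), a, gyro_smoothed$values,
                    abs_tr$fs, abs_tr$t0)
  df$open <- open_flag
  df
}

#' R index of one step window
#'
#' The FOG index R of a window is the ratio between the maximum of the
#' normalized absolute smoothed angular velocity inside the window and the
#' sEMG envelope value recorded at the same instant. Regular swing phases
#' pair a large gyro peak with a relaxed muscle (large R); shuffled or
#' attempted steps pair small angular velocity with active muscle
#' (small R). The denominator is floored at `cfg$envelope_floor`.
#'
#' @param window One-row subset of a `step_windows` data frame (or a list
#'   with `max_abs` and `i_max_abs`).
#' @param envelope [semg_envelope()] output on the same grid.
#' @param cfg A [detector_config()].
#' @return The positive scalar R.
#' @export
compute_R <- function(window, envelope, cfg = detector_config()) {
  i <- as.integer(window$i_max_abs)
  if (length(i) != 1L || is.na(i) || i < 1L || i > length(envelope$values))
    stop("compute_R: window peak index outside the envelope domain",
         call. = FALSE)
  window$max_abs / max(envelope$values[i], cfg$envelope_floor)
}

#' Classify step windows as regular, FOG or stance
#'
#' Implements the per-window decision: if the smoothed gyro minimum inside
#' the window is at or below `T2` the window is the deep stance lobe of a
#' regular step and is skipped (`stance_skip`, no R); otherwise R is
#' computed and compared with the demarcation level, `R >= R_demarcation`
#' giving `regular` (ties resolve to regular) and `R < R_demarcation`
#' giving `fog`.
#'
#' @param windows A `step_windows` data frame from [detect_step_windows()].
#' @param envelope [semg_envelope()] output on the same grid.
#' @param cfg A [detector_config()].
#' @return A data frame of class `step_classifications`: the window columns
#'   plus `R` (`NA` for stance skips) and `label` in
#'   `{regular, fog, stance_skip}`.
#' @export
classify_windows <- function(windows, envelope, cfg = detector_config()) {
  df <- as.data.frame(windows)
  k <- nrow(df)
  R <- rep(NA_real_, k)
  label <- character(k)
  for (j in seq_len(k)) {
    if (df$min_gyro[j] <= cfg$T2) {
      label[j] <- "stance_skip"
    } else {
      R[j] <- compute_R(df[j, ], envelope, cfg)
      label[j] <- if (R[j] >= cfg$R_demarcation) "regular" else "fog"
    }
  }
  df$R <- R
  df$label <- factor(label, levels = c("regular", "fog", "stance_skip"))
  class(df) <- c("step_classifications", "data.frame")
  df
}

#' Aggregate FOG-labelled windows into episodes
#'
#' Maximal runs of consecutive `fog` windows whose inter-window gaps do not
#' exceed `episode_gap_s`, kept when they contain at least
#' `min_episode_windows` windows. Episode bounds run from the first member
#' window start to the last member window end.
#'
#' @param classifications A `step_classifications` data frame.
#' @param cfg A [detector_config()].
#' @return A data frame of class `fog_episodes` with `start_s`, `end_s`,
#'   `n_windows`, `median_R`; the member row indices (into the fog subset
#'   ordering of `classifications`) are attached as attribute `members`.
#' @export
aggregate_episodes <- function(classifications, cfg = detector_config()) {
  fog <- classifications[classifications$label == "fog", , drop = FALSE]
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_windows = integer(0), median_R = numeric(0))
  class(empty) <- c("fog_episodes", "data.frame")
  if (nrow(fog) == 0L) return(empty)
  gap <- c(Inf, fog$start_s[-1] - fog$end_s[-nrow(fog)])
  grp <- cumsum(gap > cfg$episode_gap_s)
  members <- split(seq_len(nrow(fog)), grp)
  members <- members[vapply(members, length, integer(1)) >=
                       cfg$min_episode_windows]
  if (length(members) == 0L) return(empty)
  df <- data.frame(
    start_s = vapply(members, function(m) fog$start_s[m[1]], numeric(1)),
    end_s = vapply(members, function(m) fog$end_s[m[length(m)]], numeric(1)),
    n_windows = vapply(members, length, integer(1)),
    median_R = vapply(members, function(m) stats::median(fog$R[m]),
                      numeric(1)))
  rownames(df) <- NULL
  attr(df, "members") <- unname(members)
  class(df) <- c("fog_episodes", "data.frame")
  df
}

#' Step-level evaluation against reference annotations
#'
#' Each non-stance window is assigned to the annotation interval containing
#' its `t_max_abs`. Inside FOG intervals (`shuffling_fog`, `trembling_fog`)
#' a `fog` label counts as true positive and `regular` as false negative;
#' inside `regular_gait` a `fog` label is a false positive and `regular` a
#' true negative. Stance-skip windows are part of regular steps by
#' construction and are excluded from all denominators. Windows landing in
#' `rest`/`turning` intervals are tallied under `other`, windows outside
#' every annotation under `unassigned`; neither is silently dropped.
#'
#' @param classifications A `step_classifications` data frame.
#' @param annotations An [annotation_set()].
#' @return A list of class `fog_confusion` with counts `tp`, `fp`, `tn`,
#'   `fn`, `other`, `unassigned`, percentages `sensitivity` and
#'   `specificity`, and the per-window assignment table `windows` (columns
#'   `t_max_abs`, `R`, `label`, `annotation`).
#' @export
evaluate_step_level <- function(classifications, annotations) {
  validate_annotations(annotations)
  cls <- classifications[classifications$label != "stance_skip", ,
                         drop = FALSE]
  ann_label <- annotation_label_at(annotations, cls$t_max_abs)
  is_fog_ann <- ann_label %in% c("shuffling_fog", "trembling_fog")
  is_reg_ann <- ann_label %in% "regular_gait"
  pred_fog <- cls$label == "fog"
  tp <- sum(is_fog_ann & pred_fog)
  fn <- sum(is_fog_ann & !pred_fog)
  fp <- sum(is_reg_ann & pred_fog)
  tn <- sum(is_reg_ann & !pred_fog)
  other <- sum(!is.na(ann_label) & !is_fog_ann & !is_reg_ann)
  unassigned <- sum(is.na(ann_label))
  res <- list(tp = tp, fp = fp, tn = tn, fn = fn, other = other,
              unassigned = unassigned,
              sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
              specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
              windows = data.frame(t_max_abs = cls$t_max_abs, R = cls$R,
                                   label = cls$label,
                                   annotation = ann_label))
  class(res) <- "fog_confusion"
  res
}

#' @export
print.fog_confusion <- function(x, ...) {
  cat(sprintf(paste0("<fog_confusion> tp=%d fp=%d tn=%d fn=%d ",
                     "(other=%d, unassigned=%d)\n"),
              x$tp, x$fp, x$tn, x$fn, x$other, x$unassigned))
  cat(sprintf("  sensitivity = %.1f%%  specificity = %.1f%%\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Run the full detection chain on one device of a session
#'
#' Convenience wrapper: smooths and normalizes the gyro trace, computes the
#' sEMG envelope, segments step windows, classifies them with the R index
#' and aggregates FOG episodes. When the session metadata carries a
#' `gyro_full_scale_dps` entry it is used as the gyro normalization
#' constant (so low-activity recordings keep a meaningful threshold scale);
#' otherwise the observed maximum of the smoothed trace is used.
#'
#' @param session A [recording_session()].
#' @param side,muscle Which device to analyse (default right TA).
#' @param pre_cfg A [preprocess_config()].
#' @param cfg A [detector_config()].
#' @return A list of class `fog_detection` with elements `windows`,
#'   `steps` (classifications), `episodes` and `traces` (the intermediate
#'   `gyro_smoothed`, `abs` and `envelope` traces).
#' @export
detect_fog <- function(session, side = "right", muscle = "TA",
                       pre_cfg = preprocess_config(),
                       cfg = detector_config()) {
  gyro <- get_trace(session, side, muscle, "gyro_z")
  semg <- get_trace(session, side, muscle, "semg_raw")
  nc <- session$meta$gyro_full_scale_dps
  if (!is.null(nc) && (!is.numeric(nc) || nc <= 0)) nc <- NULL
  gs <- gyro_smooth(gyro, pre_cfg, norm_const = nc)
  env <- semg_envelope(semg, pre_cfg)
  ab <- abs_trace(gs)
  w <- detect_step_windows(ab, gs, cfg)
  steps <- classify_windows(w, env, cfg)
  eps <- aggregate_episodes(steps, cfg)
  structure(list(windows = w, steps = steps, episodes = eps,
                 traces = list(gyro_smoothed = gs, abs = ab, envelope = env),
                 side = side, muscle = muscle),
            class = "fog_detection")
}

#' @export
print.fog_detection <- function(x, ...) {
  tab <- table(x$steps$label)
  cat(sprintf(paste0("<fog_detection> %s/%s: %d windows ",
                     "(%d regular, %d fog, %d stance), %d episode(s)\n"),
              x$side, x$muscle, nrow(x$steps), tab[["regular"]],
              tab[["fog"]], tab[["stance_skip"]], nrow(x$episodes)))
  invisible(x)
}
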