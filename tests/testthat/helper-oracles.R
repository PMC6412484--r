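# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results by linear scans / direct
# arithmetic, independent of the package implementation.

# linear per-sample scan for threshold windows (half-open [start, end))
oracle_windows <- function(a, T1, min_win_s, fs) {
  starts <- integer(0); ends <- integer(0)
  in_win <- FALSE; st <- 0L
  for (i in seq_along(a)) {
    if (!in_win && a[i] > T1) {
      in_win <- TRUE; st <- i
    } else if (in_win && a[i] <= T1) {
      starts <- c(starts, st); ends <- c(ends, i); in_win <- FALSE
    }
  }
  keep <- (ends - starts) / fs >= min_win_s
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

# brute-force gap partition of fog windows into episodes
oracle_episodes <- function(start_s, end_s, gap_s, min_n) {
  groups <- list(); cur <- integer(0)
  for (i in seq_along(start_s)) {
    if (length(cur) && start_s[i] - end_s[cur[length(cur)]] > gap_s) {
      groups[[length(groups) + 1L]] <- cur
      cur <- integer(0)
    }
    cur <- c(cur, i)
  }
  if (length(cur)) groups[[length(groups) + 1L]] <- cur
  groups[vapply(groups, length, integer(1)) >= min_n]
}

# closed-form magnitude response of a width-w moving average at f Hz
ma_response <- function(f, w, fs) {
  ifelse(f == 0, 1, abs(sin(pi * f * w / fs) / (w * sin(pi * f / fs))))
}

# closed-form magnitude response of an FIR tap vector at f Hz
fir_response <- function(b, f, fs) {
  k <- seq_along(b) - 1
  abs(sum(b * exp(-2i * pi * f * k / fs)))
}

# a burst of 20-80 Hz band noise centred at t_c (gaussian amplitude profile)
make_burst <- function(n, fs, t_c, sigma_s, amp = 1, seed = 1) {
  set.seed(seed)
  filt <- signal::butter(2, c(20, 80) / (fs / 2), type = "pass")
  carrier <- as.numeric(signal::filtfilt(filt, rnorm(n)))
  carrier <- carrier / sd(carrier)
  t <- (0:(n - 1)) / fs
  amp * exp(-(t - t_c)^2 / (2 * sigma_s^2)) * carrier
}

# random small session for IO round trips
random_session <- function(seed, n = 50, fs = 100) {
  set.seed(seed)
  traces <- list(
    signal_trace(rnorm(n), fs, "gyro_z", "right", "TA", units = "dps"),
    signal_trace(rnorm(n), fs, "semg_raw", "right", "TA", units = "mV"),
    signal_trace(rnorm(n), fs, "semg_raw", "left", "GC", units = "mV"))
  ann <- annotation_set(c(0, 0.2), c(0.2, 0.4),
                        c("rest", "regular_gait"))
  recording_session(traces, ann, meta = list())
}

# script batteries used by the synthetic-performance checks: one session
# holding mixed FOG (shuffling + trembling) segments, one mostly regular
fog_battery_script <- function(seed) {
  gait_script(list(
    segment_spec("rest", 2),
    segment_spec("regular_gait", 8.4),       # 7 cycles
    segment_spec("shuffling_fog", 13.75),    # 25 shuffles
    segment_spec("trembling_fog", 5),
    segment_spec("rest", 2)), seed = seed)
}

regular_battery_script <- function(seed) {
  gait_script(list(
    segment_spec("rest", 2),
    segment_spec("regular_gait", 60),        # 50 cycles
    segment_spec("rest", 2)), seed = seed)
}

# pooled step-level R statistics over seeded sessions: fraction of
# FOG-annotated non-stance windows with R < demarcation, and fraction of
# regular-annotated ones with R >= demarcation
pooled_step_stats <- function(seeds, script_fun) {
  fog_below <- 0L; fog_total <- 0L; reg_above <- 0L; reg_total <- 0L
  for (sd in seeds) {
    sess <- generate_session(script_fun(sd))
    det <- detect_fog(sess)
    ev <- evaluate_step_level(det$steps, sess$annotations)
    w <- ev$windows
    is_fog_ann <- !is.na(w$annotation) &
      w$annotation %in% c("shuffling_fog", "trembling_fog")
    is_reg_ann <- !is.na(w$annotation) & w$annotation == "regular_gait"
    fog_total <- fog_total + sum(is_fog_ann)
    fog_below <- fog_below + sum(is_fog_ann & w$R < 3)
    reg_total <- reg_total + sum(is_reg_ann)
    reg_above <- reg_above + sum(is_reg_ann & w$R >= 3)
  }
  list(fog_below = fog_below, fog_total = fog_total,
       reg_above = reg_above, reg_total = reg_total)
}

# phenotype batteries: a session whose FOG content is purely one phenotype
phenotype_script <- function(kind, seed) {
  gait_script(list(
    segment_spec("rest", 1),
    segment_spec("regular_gait", 6),
    segment_spec(kind, 12.1),
    segment_spec("rest", 1)), seed = seed)
}

phenotype_pi <- function(kind, seed) {
  sess <- generate_session(phenotype_script(kind, seed))
  ann <- sess$annotations
  iv <- ann[ann$label == kind, ]
  phenotype_episode(sess, iv$start_s, iv$end_s)$PI
}
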