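fs <- 200

abs_tr_of <- function(v) abs_trace(signal_trace(v, fs, "gyro_z"))
gyro_tr_of <- function(v) signal_trace(v, fs, "gyro_z")

test_that("abs_trace rectifies pointwise and is even", {
  tr <- signal_trace(c(-0.5, 0.2), fs, "gyro_z")
  expect_equal(abs_trace(tr)$values, c(0.5, 0.2))
  expect_equal(abs_trace(signal_trace(rep(0, 5), fs, "gyro_z"))$values,
               rep(0, 5))
  for (seed in 1:5) {
    set.seed(seed)
    v <- rnorm(100)
    expect_equal(abs_trace(signal_trace(v, fs, "gyro_z"))$values,
                 abs_trace(signal_trace(-v, fs, "gyro_z"))$values)
  }
})

test_that("window segmentation handles rest, single pulses and boundaries", {
  cfg <- detector_config()
  # sub-threshold everywhere: rest, no window defined
  v <- rep(0.005, 600)
  expect_equal(nrow(detect_step_windows(abs_tr_of(v), gyro_tr_of(v), cfg)),
               0L)
  # 1 s silence, 1 s plateau, 1 s silence -> one 200-sample window
  v <- c(rep(0, 200), rep(0.5, 200), rep(0, 200))
  w <- detect_step_windows(abs_tr_of(v), gyro_tr_of(v), cfg)
  expect_equal(nrow(w), 1L)
  expect_equal(w$end_idx - w$start_idx, 200L)
  expect_equal(w$start_idx, 201L)
  # an unterminated trailing window is dropped offline
  v <- c(rep(0, 200), rep(0.5, 200))
  expect_equal(nrow(detect_step_windows(abs_tr_of(v), gyro_tr_of(v), cfg)),
               0L)
  # min-duration pruning removes chatter
  v <- rep(0, 400); v[100:102] <- 0.5
  expect_equal(nrow(detect_step_windows(abs_tr_of(v), gyro_tr_of(v), cfg)),
               0L)
  expect_equal(nrow(detect_step_windows(abs_tr_of(v), gyro_tr_of(v),
                                        detector_config(min_win_s = 0))),
               1L)
})

test_that("ten regular gait cycles give twenty raw windows", {
  sess <- generate_session(gait_script(
    list(segment_spec("regular_gait", 12)), seed = 2))
  det <- detect_fog(sess, cfg = detector_config(min_win_s = 0))
  expect_equal(nrow(det$windows), 20L)  # 10 swing + 10 stance
})

test_that("segmentation matches the brute-force linear-scan oracle", {
  cfg <- detector_config()
  for (seed in 1:50) {
    set.seed(seed)
    # random slow walk crossing the threshold repeatedly
    v <- abs(cumsum(rnorm(400, 0, 0.02)))
    w <- detect_step_windows(abs_tr_of(v), gyro_tr_of(v), cfg)
    o <- oracle_windows(v, cfg$T1, cfg$min_win_s, fs)
    if (length(v) && v[length(v)] > cfg$T1 && nrow(o)) {
      # oracle keeps no open window either (scan only emits on closing)
    }
    expect_identical(w$start_idx, o$start_idx)
    expect_identical(w$end_idx, o$end_idx)
  }
})

test_that("the R index follows the ratio formula with a floored denominator", {
  cfg <- detector_config()
  env <- signal_trace(c(0.5, 0.1, 0, 0.3, 0.8), fs, "semg_envelope")
  expect_equal(compute_R(list(max_abs = 0.8, i_max_abs = 2), env, cfg), 8)
  expect_equal(compute_R(list(max_abs = 0.8, i_max_abs = 3), env, cfg),
               0.8 / 1e-6)
  expect_equal(compute_R(list(max_abs = 0.3, i_max_abs = 4), env, cfg), 1)
  expect_error(compute_R(list(max_abs = 0.3, i_max_abs = 9), env, cfg),
               "outside")
})

test_that("window classification applies the stance rule then demarcation", {
  cfg <- detector_config()
  env <- signal_trace(rep(0.1, 100), fs, "semg_envelope")
  w <- data.frame(start_idx = c(1L, 21L, 41L), end_idx = c(11L, 31L, 51L),
                  start_s = c(0, 0.1, 0.2), end_s = c(0.05, 0.15, 0.25),
                  i_max_abs = c(5L, 25L, 45L),
                  t_max_abs = c(0.02, 0.12, 0.22),
                  max_abs = c(0.9, 0.8, 0.12),
                  min_gyro = c(-0.6, -0.1, -0.1))
  cls <- classify_windows(w, env, cfg)
  expect_equal(as.character(cls$label), c("stance_skip", "regular", "fog"))
  expect_true(is.na(cls$R[1]))
  expect_equal(cls$R[2], 8)   # R >= 3 -> regular
  expect_equal(cls$R[3], 1.2) # R < 3 -> fog
  # tie at the demarcation level resolves to regular (values exact in
  # binary so R == 3 precisely)
  env3 <- signal_trace(rep(0.25, 100), fs, "semg_envelope")
  w1 <- w[2, ]; w1$max_abs <- 0.75
  cls1 <- classify_windows(w1, env3, cfg)
  expect_equal(cls1$R, 3)
  expect_equal(as.character(cls1$label), "regular")
})

test_that("episode aggregation matches the brute-force gap partition", {
  cfg <- detector_config()
  mk_cls <- function(start_s, end_s, label) {
    df <- data.frame(start_s = start_s, end_s = end_s,
                     R = ifelse(label == "fog", 1, 5),
                     label = factor(label,
                                    levels = c("regular", "fog",
                                               "stance_skip")))
    class(df) <- c("step_classifications", "data.frame")
    df
  }
  expect_equal(nrow(aggregate_episodes(
    mk_cls(c(0, 1), c(0.5, 1.5), c("regular", "regular")), cfg)), 0L)
  # five fog windows 0.3 s apart -> one episode
  st <- seq(0, by = 0.5, length.out = 5)
  ep <- aggregate_episodes(mk_cls(st, st + 0.2, rep("fog", 5)), cfg)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$start_s, 0)
  expect_equal(ep$end_s, st[5] + 0.2)
  # 3 fog, 2 s silence, 3 fog -> two episodes
  st <- c(0, 0.5, 1.0, 3.2, 3.7, 4.2)
  ep <- aggregate_episodes(mk_cls(st, st + 0.2, rep("fog", 6)), cfg)
  expect_equal(nrow(ep), 2L)
  # random cases against the oracle
  for (seed in 1:30) {
    set.seed(seed)
    k <- sample(1:12, 1)
    st <- cumsum(runif(k, 0.1, 2))
    en <- st + runif(k, 0.05, 0.3)
    ep <- aggregate_episodes(mk_cls(st, en, rep("fog", k)), cfg)
    o <- oracle_episodes(st, en, cfg$episode_gap_s,
                         cfg$min_episode_windows)
    expect_equal(nrow(ep), length(o))
    if (length(o)) {
      expect_equal(ep$start_s,
                   vapply(o, function(m) st[m[1]], numeric(1)))
      expect_equal(ep$end_s,
                   vapply(o, function(m) en[m[length(m)]], numeric(1)))
    }
  }
})

test_that("step-level evaluation counts match an independent recount", {
  labels <- c("regular", "fog")
  for (seed in 1:20) {
    set.seed(seed)
    k <- 40
    t_max <- sort(runif(k, 0, 10))
    pred <- sample(c(labels, "stance_skip"), k, replace = TRUE)
    cls <- data.frame(t_max_abs = t_max, R = runif(k, 0.5, 6),
                      label = factor(pred, levels = c("regular", "fog",
                                                      "stance_skip")))
    ann <- annotation_set(c(0, 3, 6, 8), c(3, 6, 8, 9.5),
                          c("regular_gait", "shuffling_fog", "rest",
                            "trembling_fog"))
    ev <- evaluate_step_level(cls, ann)
    # brute-force recount
    ref <- annotation_label_at(ann, t_max)
    nonstance <- pred != "stance_skip"
    expect_equal(ev$tp, sum(nonstance & pred == "fog" &
                              ref %in% c("shuffling_fog", "trembling_fog"),
                            na.rm = TRUE))
    expect_equal(ev$fn, sum(nonstance & pred == "regular" &
                              ref %in% c("shuffling_fog", "trembling_fog"),
                            na.rm = TRUE))
    expect_equal(ev$fp, sum(nonstance & pred == "fog" &
                              ref %in% "regular_gait", na.rm = TRUE))
    expect_equal(ev$tn, sum(nonstance & pred == "regular" &
                              ref %in% "regular_gait", na.rm = TRUE))
    expect_equal(ev$other, sum(nonstance & !is.na(ref) &
                                 ref == "rest"))
    expect_equal(ev$unassigned, sum(nonstance & is.na(ref)))
    expect_equal(ev$tp + ev$fn + ev$fp + ev$tn + ev$other + ev$unassigned,
                 sum(nonstance))
  }
})

test_that("perfect synthetic annotations give 100% sensitivity/specificity", {
  sess <- generate_session(default_tug_script(seed = 12))
  det <- detect_fog(sess)
  ev <- evaluate_step_level(det$steps, sess$annotations)
  expect_equal(ev$fp, 0L)
  expect_equal(ev$fn, 0L)
  expect_gt(ev$tp, 20)
  expect_gt(ev$tn, 10)
})

test_that("R values are invariant to a common gyro scale before normalization", {
  sess <- generate_session(default_tug_script(seed = 4))
  sess$meta$gyro_full_scale_dps <- NULL  # use observed-max normalization
  d1 <- detect_fog(sess)
  tr <- get_trace(sess, "right", "TA", "gyro_z")
  tr$values <- tr$values * 12.5
  d2 <- detect_fog(put_trace(sess, tr))
  expect_identical(d1$windows$start_idx, d2$windows$start_idx)
  expect_equal(d1$steps$R, d2$steps$R, tolerance = 1e-9)
})

test_that("streaming segmentation equals offline on identical input", {
  sess <- generate_session(default_tug_script(seed = 9))
  det <- detect_fog(sess)
  for (chunk in c(0.1, 0.5, 2)) {
    ws <- detect_step_windows_stream(det$traces$abs,
                                     det$traces$gyro_smoothed,
                                     chunk_s = chunk)
    expect_identical(ws$start_idx, det$windows$start_idx)
    expect_identical(ws$end_idx, det$windows$end_idx)
    cls_s <- classify_windows(ws[names(ws) != "open"],
                              det$traces$envelope)
    expect_equal(cls_s$R, det$steps$R, tolerance = 1e-9)
  }
})
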