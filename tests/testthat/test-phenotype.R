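fs <- 200

test_that("the fused product multiplies traces pointwise", {
  n <- 1000
  t <- (0:(n - 1)) / fs
  env0 <- signal_trace(rep(0, n), fs, "semg_envelope", "right", "TA")
  gy <- signal_trace(sin(2 * pi * 1.5 * t), fs, "gyro_z", "right", "TA")
  expect_equal(fuse_product(env0, gy)$values, rep(0, n))
  env1 <- signal_trace(rep(1, n), fs, "semg_envelope", "right", "TA")
  expect_equal(fuse_product(env1, gy)$values, gy$values)
  gl <- signal_trace(sin(t), fs, "gyro_z", "left", "TA")
  expect_error(fuse_product(env1, gl), "same side")
})

test_that("shuffling product peaks are negative (sEMG maxima at gyro minima)", {
  sess <- generate_session(phenotype_script("shuffling_fog", seed = 21))
  ann <- sess$annotations
  iv <- ann[ann$label == "shuffling_fog", ]
  gyro <- normalize_abs_max(get_trace(sess, "right", "TA", "gyro_z"))
  env <- semg_envelope(get_trace(sess, "right", "TA", "semg_raw"))
  pr <- fuse_product(slice_trace(env, iv$start_s, iv$end_s),
                     slice_trace(gyro, iv$start_s, iv$end_s))
  v <- fir_lowpass(pr)$values
  loc <- which(diff(sign(diff(abs(v)))) == -2) + 1
  big <- loc[abs(v[loc]) > 0.5 * max(abs(v))]
  expect_gt(length(big), 5)
  expect_true(all(v[big] < 0))
})

test_that("FIR low-pass has unity DC gain and matches its closed form", {
  cfg <- phenotype_config()
  tr <- signal_trace(rep(2, 600), fs, "fused")
  expect_equal(fir_lowpass(tr, cfg)$values[200:400], rep(2, 201),
               tolerance = 1e-12)
  b <- signal::fir1(cfg$fir_taps - 1L, cfg$fir_cutoff_hz / (fs / 2),
                    type = "low")
  b <- as.numeric(b) / sum(b)
  t <- (0:3999) / fs
  for (f0 in c(0.7, 1.5, 5)) {
    y <- fir_lowpass(signal_trace(sin(2 * pi * f0 * t), fs, "fused"),
                     cfg)$values
    emp <- max(abs(y[1000:3000]))
    expect_lt(abs(emp - fir_response(b, f0, fs)), 0.01)
  }
  # 5 Hz tone lands deep in the stopband
  y5 <- fir_lowpass(signal_trace(sin(2 * pi * 5 * t), fs, "fused"),
                    cfg)$values
  expect_lt(max(abs(y5[1000:3000])), 10^(-40 / 20))
  expect_error(fir_lowpass(signal_trace(rnorm(50), fs, "fused"), cfg),
               "fir_taps")
})

test_that("bilateral subtraction cancels, doubles antiphase, adds variances", {
  n <- 20000
  t <- (0:(n - 1)) / fs
  mk <- function(v, side) signal_trace(v, fs, "fused", side, "TA")
  x <- sin(2 * pi * 1.2 * t)
  expect_equal(bilateral_subtract(mk(x, "right"), mk(x, "left"))$values,
               rep(0, n))
  d <- bilateral_subtract(mk(x, "right"), mk(-x, "left"))
  expect_equal(d$values, 2 * x)
  set.seed(31)
  r <- rnorm(n, 0, 1.3); l <- rnorm(n, 0, 0.7)
  d <- bilateral_subtract(mk(r, "right"), mk(l, "left"))
  expect_lt(abs(var(d$values) / (var(r) + var(l)) - 1), 0.1)
})

test_that("PSD locates spectral lines and satisfies Parseval exactly", {
  n <- 4000
  t <- (0:(n - 1)) / fs
  for (f0 in c(0.75, 1.3)) {
    tr <- signal_trace(sin(2 * pi * f0 * t), fs, "fused")
    sp <- compute_psd(tr, phenotype_config(psd_method = "periodogram"))
    expect_lt(abs(sp$freqs[which.max(sp$psd)] - f0), sp$df)
  }
  for (seed in 1:5) {
    set.seed(seed)
    x <- rnorm(2048)
    sp <- compute_psd(signal_trace(x, fs, "fused"),
                      phenotype_config(psd_method = "periodogram"))
    expect_lt(abs(sum(sp$psd) * sp$df / mean((x - mean(x))^2) - 1), 0.01)
    # Welch-averaged white noise shows no dominant line
    spw <- compute_psd(signal_trace(x, fs, "fused"), phenotype_config())
    expect_lt(max(spw$psd) / mean(spw$psd), 5)
  }
  expect_error(compute_psd(signal_trace(rnorm(100), fs, "fused")),
               "shorter than 2 s")
})

test_that("the phenotype index is max over geometric mean with a floor", {
  freqs <- seq(0.25, 2, by = 0.25)
  expect_equal(phenotype_index(rep(3.3, 8), freqs), 1)
  expect_equal(phenotype_index(c(1, 1, 1, 100), c(0.5, 1, 1.5, 2)),
               100 / 100^(1 / 4))
  # uniform scaling leaves PI unchanged
  set.seed(2)
  p <- rexp(8)
  expect_equal(phenotype_index(p, freqs),
               phenotype_index(123.4 * p, freqs), tolerance = 1e-12)
  expect_gte(phenotype_index(p, freqs), 1)
  # DC bin excluded; too-narrow bands rejected
  expect_error(phenotype_index(c(9, 1, 1, 1), c(0, 0.9, 1.8, 2.7)),
               "fewer than 4")
})

test_that("phenotype labels follow the threshold with ties to shuffling", {
  cfg <- phenotype_config()
  expect_equal(classify_phenotype(109.34, cfg), "shuffling")
  expect_equal(classify_phenotype(3.18, cfg), "trembling")
  expect_equal(classify_phenotype(cfg$pi_threshold, cfg), "shuffling")
})

test_that("FIR filtering and bilateral subtraction commute", {
  sess <- generate_session(phenotype_script("shuffling_fog", seed = 8))
  ann <- sess$annotations
  iv <- ann[ann$label == "shuffling_fog", ]
  legs <- lapply(c("right", "left"), function(side) {
    gyro <- normalize_abs_max(get_trace(sess, side, "TA", "gyro_z"))
    env <- semg_envelope(get_trace(sess, side, "TA", "semg_raw"))
    fuse_product(slice_trace(env, iv$start_s, iv$end_s),
                 slice_trace(gyro, iv$start_s, iv$end_s))
  })
  a <- bilateral_subtract(fir_lowpass(legs[[1]]), fir_lowpass(legs[[2]]))
  b <- fir_lowpass(bilateral_subtract(legs[[1]], legs[[2]]))
  expect_equal(a$values, b$values, tolerance = 1e-10)
})

test_that("shuffling and trembling PI populations separate", {
  pis <- lapply(c("shuffling_fog", "trembling_fog"), function(kind)
    vapply(1:6, function(s) phenotype_pi(kind, 100 + s), numeric(1)))
  expect_gt(min(pis[[1]]), max(pis[[2]]))
  expect_gt(mean(pis[[1]]) / mean(pis[[2]]), 10)
  expect_true(all(vapply(pis[[1]], classify_phenotype, character(1)) ==
                    "shuffling"))
  expect_true(all(vapply(pis[[2]], classify_phenotype, character(1)) ==
                    "trembling"))
})
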