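test_that("trace construction enforces the domain invariants", {
  expect_error(signal_trace(numeric(0), 100), "length >= 1")
  expect_error(signal_trace(c(1, NA), 100), "finite")
  expect_error(signal_trace(1:3, 0), "positive")
  expect_error(signal_trace(c(-0.1, 0.5), 100, channel = "semg_envelope"),
               "\\[0, 1\\]")
  expect_error(signal_trace(c(0, 0), 100, normalized = TRUE), "all-zero")
  expect_error(signal_trace(c(0.3, 0.5), 100, normalized = TRUE),
               "max\\(\\|values\\|\\)")
  tr <- signal_trace(c(0.5, -1), 200, normalized = TRUE)
  expect_s3_class(tr, "signal_trace")
  expect_equal(trace_times(tr), c(0, 1 / 200))
})

test_that("normalize_abs_max scales to unit maximum and preserves signs", {
  tr <- signal_trace(c(2, -4, 1), 100)
  out <- normalize_abs_max(tr)
  expect_equal(out$values, c(0.5, -1, 0.25))
  expect_true(out$normalized)
  expect_equal(out$norm_const, 4)
  # idempotence
  expect_equal(normalize_abs_max(out)$values, out$values)
  expect_error(normalize_abs_max(signal_trace(c(0, 0), 10)), "all-zero")
})

test_that("normalization is scale-invariant and invertible on random traces", {
  for (seed in 1:10) {
    set.seed(seed)
    v <- rnorm(40) * 10^runif(1, -3, 3)
    c_pos <- 10^runif(1, -2, 2)
    a <- normalize_abs_max(signal_trace(v, 50))
    b <- normalize_abs_max(signal_trace(c_pos * v, 50))
    expect_equal(max(abs(a$values)), 1)
    expect_equal(a$values, b$values, tolerance = 1e-12)
    expect_equal(a$values * a$norm_const, v, tolerance = 1e-12)
  }
})

test_that("sessions reject duplicate keys and mismatched grids", {
  t1 <- signal_trace(1:5, 100, "gyro_z", "right", "TA")
  t2 <- signal_trace(1:5, 100, "gyro_z", "right", "TA")
  expect_error(recording_session(list(t1, t2)), "duplicate")
  t3 <- signal_trace(1:4, 100, "semg_raw", "right", "TA")
  expect_error(recording_session(list(t1, t3)), "share fs and length")
  s <- recording_session(list(t1))
  expect_identical(get_trace(s, "right", "TA", "gyro_z")$values,
                   as.numeric(1:5))
  expect_error(get_trace(s, "left", "TA", "gyro_z"), "no trace")
})

test_that("annotation validation enforces vocabulary, order and disjointness", {
  expect_error(annotation_set(0, 1, "strolling"), "unknown annotation")
  expect_error(annotation_set(1, 1, "rest"), "start_s < end_s")
  expect_error(annotation_set(c(0, 1), c(1.5, 2),
                              c("rest", "regular_gait")), "overlap")
  ann <- annotation_set(c(2, 0), c(3, 1), c("regular_gait", "rest"))
  expect_equal(ann$start_s, c(0, 2))  # sorted on construction
  expect_equal(annotation_label_at(ann, c(0.5, 1.5, 2)),
               c("rest", NA, "regular_gait"))
})

test_that("trace files parse, map columns by name and reject bad input", {
  d <- withr::local_tempdir()
  f <- file.path(d, "session.csv")
  n <- 1000
  t <- (0:(n - 1)) / 200
  writeLines(c("t_s,right_TA_gyro_z,right_TA_semg_raw",
               sprintf("%.10g,%.10g,%.10g", t, sin(t), cos(t))), f)
  s <- read_trace_file(f)
  expect_length(s$traces, 2)
  expect_equal(length(get_trace(s, "right", "TA", "gyro_z")$values), n)
  expect_equal(get_trace(s, "right", "TA", "gyro_z")$fs, 200)

  f2 <- file.path(d, "dup.csv")
  writeLines(c("t_s,right_TA_gyro_z,right_TA_gyro_z", "0,1,2", "0.01,1,2"),
             f2)
  expect_error(read_trace_file(f2), "schema error.*duplicated")

  f3 <- file.path(d, "nonmono.csv")
  writeLines(c("t_s,right_TA_gyro_z", "0,1", "0.02,1", "0.01,1"), f3)
  expect_error(read_trace_file(f3), "format error")

  f4 <- file.path(d, "nan.csv")
  writeLines(c("t_s,right_TA_gyro_z", "0,1", "0.01,NA"), f4)
  expect_error(read_trace_file(f4), "format error")

  f5 <- file.path(d, "odd.csv")
  writeLines(c("t_s,mystery", "0,1", "0.01,1"), f5)
  expect_error(read_trace_file(f5), "schema error.*cannot map")
  s5 <- read_trace_file(f5, schema = list(
    mystery = list(side = "left", muscle = "GC", channel = "semg_raw")))
  expect_equal(names(s5$traces), "left_GC_semg_raw")
})

test_that("write then read round-trips sessions and annotations", {
  d <- withr::local_tempdir()
  for (seed in 1:5) {
    s <- random_session(seed)
    f <- file.path(d, sprintf("s%d.csv", seed))
    fa <- file.path(d, sprintf("a%d.csv", seed))
    write_trace_file(s, f)
    write_annotations(s$annotations, fa)
    s2 <- read_trace_file(f, annotations = fa)
    expect_setequal(names(s2$traces), names(s$traces))
    for (k in names(s$traces))
      expect_equal(s2$traces[[k]]$values, s$traces[[k]]$values,
                   tolerance = 1e-12)
    expect_equal(as.data.frame(s2$annotations),
                 as.data.frame(s$annotations), tolerance = 1e-12)
  }
  # empty annotation set -> header-only file
  fe <- file.path(d, "empty.csv")
  write_annotations(annotation_set(), fe)
  expect_identical(readLines(fe), "start_s,end_s,label")
  expect_equal(nrow(read_annotations(fe)), 0L)
})

test_that("loading can resample all channels onto one common rate", {
  d <- withr::local_tempdir()
  f <- file.path(d, "hi.csv")
  t <- (0:999) / 1000
  writeLines(c("t_s,right_TA_gyro_z",
               sprintf("%.10g,%.10g", t, sin(2 * pi * 2 * t))), f)
  s <- read_trace_file(f, resample_fs = 200)
  tr <- get_trace(s, "right", "TA", "gyro_z")
  expect_equal(tr$fs, 200)
  expect_equal(tr$values, sin(2 * pi * 2 * trace_times(tr)),
               tolerance = 1e-3)
})
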