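test_that("load_timeseries validates shape and contents", {
  d <- withr::local_tempdir()
  f <- file.path(d, "ts.csv")
  m <- matrix(1:12, 4, 3)
  write.table(m, f, sep = ",", row.names = FALSE, col.names = FALSE)
  ts <- load_timeseries(f, tr_seconds = 0.72)
  expect_equal(dim(ts$data), c(4L, 3L))
  expect_equal(unname(ts$data), matrix(as.numeric(1:12), 4, 3))

  # NaN cell named by position
  m2 <- m
  m2[3, 2] <- NaN
  write.table(m2, f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_error(load_timeseries(f, 0.72), "row 3, column 2")

  # fewer than 2 rows
  write.table(m[1, , drop = FALSE], f, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_error(load_timeseries(f, 0.72), "fewer than 2")
})

test_that("write -> load round-trips the matrix and labels", {
  d <- withr::local_tempdir()
  set.seed(1)
  ts <- bold_timeseries(matrix(rnorm(60), 10, 6), 0.72,
                        region_labels = sprintf("roi%02d", 1:6),
                        subject_id = "s1", condition = "REST")
  for (ext in c("csv", "tsv")) {
    f <- file.path(d, paste0("rt.", ext))
    write_timeseries(ts, f)
    back <- load_timeseries(f, 0.72)
    expect_equal(unname(back$data), unname(ts$data), tolerance = 1e-12)
    expect_equal(back$region_labels, ts$region_labels)
  }
})

test_that("wide matrices transpose only when permitted", {
  d <- withr::local_tempdir()
  f <- file.path(d, "wide.csv")
  write.table(matrix(rnorm(30), 3, 10), f, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_warning(ts <- load_timeseries(f, 0.72, allow_transpose = TRUE),
                 "transposing")
  expect_equal(dim(ts$data), c(10L, 3L))
})

test_that("band-pass filter removes DC and matches the analytic gain", {
  tr <- 0.72
  # constant column: high-pass side suppresses it entirely
  ts <- bold_timeseries(cbind(rep(7, 400), rep(-2, 400)), tr)
  out <- bandpass_filter(ts)
  expect_lt(max(abs(out$data)), 1e-6)

  # in-band and out-of-band sinusoids against the analytic Butterworth
  # magnitude response (applied twice: zero-phase = forward + backward)
  t <- (0:1999) * tr
  spec <- filter_spec()
  for (f0 in c(0.04, 0.2)) {
    x <- bold_timeseries(cbind(sin(2 * pi * f0 * t), cos(2 * pi * f0 * t)), tr)
    y <- bandpass_filter(x, spec)$data
    amp <- max(abs(y[500:1500, 1]))
    gain2 <- lgec:::butter_bandpass_gain(spec, f0, 1 / tr)^2
    expect_equal(amp, gain2, tolerance = 0.02)
  }
  # the paper's band keeps 0.04 Hz essentially intact and crushes 0.2 Hz
  expect_gt(lgec:::butter_bandpass_gain(spec, 0.04, 1 / tr)^2, 0.95)
  expect_lt(lgec:::butter_bandpass_gain(spec, 0.2, 1 / tr)^2, 0.5)
})

test_that("filtering is linear and rejects infeasible bands", {
  set.seed(2)
  tr <- 0.72
  x <- matrix(rnorm(600), 300, 2)
  y <- matrix(rnorm(600), 300, 2)
  fx <- bandpass_filter(bold_timeseries(x, tr))$data
  fy <- bandpass_filter(bold_timeseries(y, tr))$data
  fxy <- bandpass_filter(bold_timeseries(2 * x - 3 * y, tr))$data
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-10)

  expect_error(bandpass_filter(bold_timeseries(x, tr = 10)),
               "infeasible band")
})

test_that("trim_edges drops floor(fraction * T) frames per end", {
  mk <- function(T) bold_timeseries(matrix(seq_len(2 * T), T, 2), 0.72)
  expect_equal(nrow(trim_edges(mk(100), 0.05)$data), 90L)
  expect_equal(nrow(trim_edges(mk(20), 0.05)$data), 18L)
  ts <- mk(50)
  expect_identical(trim_edges(ts, 0)$data, ts$data)
  # first kept frame is frame k + 1
  expect_equal(unname(trim_edges(mk(100), 0.05)$data[1, 1]), 6)
  # trimming twice with fraction 0 is still the single trim
  once <- trim_edges(ts, 0.1)
  expect_identical(trim_edges(once, 0)$data, once$data)
  # trimming commutes with column selection
  sub <- bold_timeseries(ts$data[, 1:2], 0.72)
  expect_equal(trim_edges(sub, 0.1)$data, trim_edges(ts, 0.1)$data[, 1:2])
  expect_error(trim_edges(mk(3), 0.4), "fewer than 2")
})

test_that("pattern sets split by subject and z-score on training frames", {
  series <- make_rank_data(10, 100, 8, 3, 0.1, seed = 5)
  ps <- build_pattern_set(series, train_frac = 0.9, seed = 3)
  expect_equal(nrow(ps$patterns), 1000L)
  expect_equal(sum(ps$train_mask), 900L)
  expect_length(ps$test_subjects, 1L)
  # split is a partition and subject-aligned
  expect_setequal(unique(ps$subject[!ps$train_mask]), ps$test_subjects)
  expect_false(any(ps$subject[ps$train_mask] %in% ps$test_subjects))
  # training frames are z-scored per region
  tr <- ps$patterns[ps$train_mask, ]
  expect_lt(max(abs(colMeans(tr))), 1e-10)
  expect_lt(max(abs(apply(tr, 2, sd) - 1)), 1e-10)
  # normalization is invertible
  raw <- do.call(rbind, lapply(series, function(s) s$data))
  expect_equal(lgec:::invert_normalization(ps$patterns, ps$normalization),
               raw, tolerance = 1e-12, ignore_attr = TRUE)
  # determinism
  ps2 <- build_pattern_set(series, train_frac = 0.9, seed = 3)
  expect_identical(ps$train_mask, ps2$train_mask)
  # inconsistent widths rejected
  bad <- c(series, list(bold_timeseries(matrix(rnorm(30), 10, 3), 0.72)))
  expect_error(build_pattern_set(bad, seed = 1), "same number of regions")
})
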