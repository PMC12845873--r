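# Loading, filtering/resampling, mastoid re-referencing.

test_that("delimited and EDF files round-trip a recording", {
  rec <- tiny_recording(duration = 4, n_channels = 19, seed = 7)
  rec$channel_names <- default_channels(19)
  rownames(rec$data) <- rec$channel_names
  d <- withr::local_tempdir()

  tsv <- file.path(d, "a.tsv")
  write_recording_tsv(rec, tsv)
  r1 <- read_recording(tsv)
  expect_identical(r1$channel_names, rec$channel_names)
  expect_equal(r1$sampling_rate, 250)
  expect_equal(dim(r1$data), c(19, 1000))
  expect_lt(max(abs(r1$data - rec$data)), 1e-8)

  edf <- file.path(d, "a.edf")
  write_recording_edf(rec, edf)
  r2 <- read_recording(edf)
  expect_identical(r2$channel_names, rec$channel_names)
  expect_equal(r2$sampling_rate, 250)
  qstep <- max(apply(rec$data, 1, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(r2$data - rec$data)), qstep)
})

test_that("unreadable or truncated files raise I/O errors", {
  expect_error(read_recording("no/such/file.tsv"), "not found")
  d <- withr::local_tempdir()
  rec <- tiny_recording(duration = 2, seed = 1)
  edf <- file.path(d, "t.edf")
  write_recording_edf(rec, edf)
  full <- readBin(edf, "raw", file.info(edf)$size)
  writeBin(full[1:3000], file.path(d, "trunc.edf"))
  expect_error(read_recording(file.path(d, "trunc.edf")), "truncated")
  writeLines(c("# sampling_rate: 250", "a\t1\t2", "b\t1"), file.path(d, "ragged.tsv"))
  expect_error(read_recording(file.path(d, "ragged.tsv")), "row lengths")
})

test_that("filter_resample halves the sample count and shapes the spectrum", {
  fs <- 500
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  mk <- function(f) recording(rbind(sin(2 * pi * f * t), cos(2 * pi * f * t)),
                              sampling_rate = fs)
  out <- filter_resample(mk(10), target_rate = 250)
  expect_equal(out$sampling_rate, 250)
  expect_lte(abs(ncol(out$data) - length(t) / 2), 1)

  # sinusoid-fit amplitude oracle: project onto quadrature pair at f
  amp_at <- function(x, f, rate) {
    tt <- seq_along(x) / rate
    2 * sqrt(mean(x * sin(2 * pi * f * tt))^2 + mean(x * cos(2 * pi * f * tt))^2)
  }
  mid <- function(x) x[round(length(x) * 0.25):round(length(x) * 0.75)]
  a10 <- amp_at(mid(filter_resample(mk(10), target_rate = 500)$data[1, ]), 10, 500)
  expect_lt(abs(20 * log10(a10 / 1)), 1)          # within 1 dB
  a50 <- amp_at(mid(filter_resample(mk(50), target_rate = 500)$data[1, ]), 50, 500)
  expect_lt(20 * log10(a50 / 1), -20)             # >= 20 dB down
  expect_error(filter_resample(mk(10), band_high = 300), "Nyquist")
})

test_that("filtering is linear and rate-idempotent", {
  fs <- 250
  n <- 1000
  x <- recording(matrix(rnorm(2 * n), 2), fs)
  y <- recording(matrix(rnorm(2 * n), 2), fs)
  f <- function(r) filter_resample(r, target_rate = fs)
  lhs <- f(recording(2 * x$data - 3 * y$data, fs))$data
  rhs <- 2 * f(x)$data - 3 * f(y)$data
  expect_equal(lhs, rhs, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(ncol(f(x)$data), n)
})

test_that("mastoid re-referencing drops channels and is invertible", {
  rec <- tiny_recording(duration = 2, n_channels = 19, seed = 9)
  rec$channel_names <- default_channels(19)
  rownames(rec$data) <- rec$channel_names
  rr <- rereference_select(rec)
  expect_equal(nrow(rr$data), 17)
  expect_false(any(c("M1", "M2") %in% rr$channel_names))
  back <- rr$data + rep(attr(rr, "reference"), each = 17)
  expect_lt(max(abs(back - rec$data[rr$channel_names, ])), 1e-10)

  # zero mastoids: data unchanged except channel removal
  rec0 <- rec
  rec0$data[c("M1", "M2"), ] <- 0
  rr0 <- rereference_select(rec0)
  expect_equal(rr0$data, rec0$data[rr0$channel_names, ])

  # missing mastoids: pass-through with a notice
  r17 <- tiny_recording(duration = 2, seed = 2)
  expect_message(out <- rereference_select(r17), "pass-through")
  expect_identical(out$data, r17$data)
  rec1 <- rec
  rec1$channel_names[19] <- "XX"
  rownames(rec1$data) <- rec1$channel_names
  expect_error(rereference_select(rec1), "missing")
})
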