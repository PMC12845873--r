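# Synthetic EEG generator: templates, semi-Markov dynamics, recordings,
# cohorts.

test_that("templates are zero-mean, unit-norm, mutually uncorrelated and seeded", {
  tm1 <- make_templates(17, 4, seed = 1)
  tm2 <- make_templates(17, 4, seed = 1)
  expect_identical(tm1, tm2)
  expect_lt(max(abs(rowMeans(tm1))), 1e-12)
  expect_equal(unname(rowSums(tm1^2)), rep(1, 4), tolerance = 1e-12)
  # correlation oracle over the 6 pairs
  cc <- stats::cor(t(tm1))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.5)
  expect_error(make_templates(3, 4), "n_channels")
})

test_that("forced two-state transitions alternate strictly", {
  tm <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  p <- synth_params(n_channels = 8, duration = 20, k = 2,
                    transition_matrix = tm, duration_mean_ms = 400, seed = 2)
  gt <- simulate_state_sequence(p)
  cls <- rle(gt$state_sequence)$values
  expect_true(all(diff(cls) != 0))
  expect_setequal(unique(cls), 1:2)
})

test_that("segment durations match the requested mean and runs are seeded", {
  p <- synth_params(duration = 600, duration_mean_ms = 80, seed = 3)
  gt <- simulate_state_sequence(p)
  expect_length(gt$state_sequence, 600 * 250)
  mean_ms <- mean(rle(gt$state_sequence)$lengths) * 1000 / 250
  expect_lt(abs(mean_ms - 80) / 80, 0.15)
  gt2 <- simulate_state_sequence(p)
  expect_identical(gt$state_sequence, gt2$state_sequence)
  bad <- p
  bad$transition_matrix[1, ] <- 0
  expect_error(simulate_state_sequence(bad), "sum to 1|degenerate")
})

test_that("recordings have the right shape, SNR and noiseless topographies", {
  p <- synth_params(duration = 60, snr = 4, seed = 5)
  gt <- simulate_state_sequence(p)
  rec <- synthesize_recording(p, gt)
  expect_equal(dim(rec$data), c(17, 15000))
  comp <- attr(rec, "components")
  snr_hat <- mean(comp$signal^2) / mean(comp$noise^2)
  expect_lt(abs(snr_hat - 4) / 4, 0.10)

  # noiseless limit: topography at envelope maxima matches the template
  p0 <- synth_params(duration = 4, snr = 1e12, drift_amplitude = 0, seed = 6)
  gt0 <- simulate_state_sequence(p0)
  rec0 <- synthesize_recording(p0, gt0)
  tmpl <- attr(rec0, "components")$templates
  tvec <- (seq_len(ncol(rec0$data)) - 1) / 250
  peaks <- which(abs(sin(2 * pi * 10 * tvec)) > 0.95)
  rr <- vapply(peaks, function(t)
    abs(stats::cor(rec0$data[, t], tmpl[gt0$state_sequence[t], ])), numeric(1))
  expect_true(all(rr >= 0.99))
})

test_that("cohorts are bookkept, reproducible, and share templates", {
  p <- synth_params(duration = 5, seed = 1)
  spec <- list(list(params = p, n_subjects = 10, group_label = "HC"),
               list(params = p, n_subjects = 10, group_label = "SCZ"))
  co <- generate_cohort(spec, seed = 4)
  expect_length(co$recordings, 20)
  expect_equal(vapply(co$recordings, function(r) r$group_label, ""),
               rep(c("HC", "SCZ"), each = 10))
  co2 <- generate_cohort(spec, seed = 4)
  expect_identical(co$recordings, co2$recordings)
  tpl <- lapply(co$truths, `[[`, "templates")
  expect_identical(tpl[[1]], tpl[[20]])
  expect_error(generate_cohort(list(list(params = p, n_subjects = 0,
                                         group_label = "X")), 1),
               "n_subjects")
})

test_that("generated dynamics converge to the requested transition matrix", {
  tm <- matrix(1 / 3, 4, 4); diag(tm) <- 0
  tm[2, ] <- c(0.2, 0, 0.2, 0.6)
  p <- synth_params(duration = 300, transition_matrix = tm, seed = 8)
  gt <- simulate_state_sequence(p)
  seg <- segmentation(gt$state_sequence, 250)
  emp <- attr(compute_parameters(seg), "transition_matrix")
  expect_lt(max(abs(emp - tm)), 0.05)
})

test_that("cohort round-trips through the on-disk layout", {
  p <- synth_params(duration = 2, seed = 3)
  co <- generate_cohort(list(list(params = p, n_subjects = 2,
                                  group_label = "HC")), seed = 2)
  d <- withr::local_tempdir()
  man <- write_cohort(co, d)
  expect_true(file.exists(file.path(d, "manifest.tsv")))
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  r <- read_recording(file.path(d, man$file[1]), group_label = man$group_label[1])
  expect_equal(r$data, co$recordings[[1]]$data, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(r$sampling_rate, 250)
})
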