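# GFP, peak sampling, modified K-means, canonical labelling, backfitting,
# microstate parameters.

test_that("gfp matches the population-SD formula", {
  r <- recording(matrix(3.7, 4, 5), 250)
  expect_equal(gfp(r)$values, rep(0, 5))
  r2 <- recording(matrix(c(1, -1), 2, 3), 250)
  expect_equal(gfp(r2)$values, rep(1, 3))
  x <- matrix(rnorm(17 * 10), 17)
  g <- gfp(recording(x, 250))$values
  oracle <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_equal(g, oracle, tolerance = 1e-12)
  expect_error(gfp(recording(matrix(1, 1, 5), 250)), "2 channels")
})

test_that("gfp peaks are strict interior local maxima", {
  expect_equal(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2, 4))
  expect_length(find_gfp_peaks(rep(1, 10)), 0)
  # rectified 10 Hz envelope at 250 Hz: 20 peaks per second
  tm <- make_templates(8, 2, seed = 1)
  tt <- (0:249) / 250
  rec <- recording(outer(tm[1, ], sin(2 * pi * 10 * tt)), 250)
  expect_length(find_gfp_peaks(gfp(rec)), 20)
})

test_that("peak map sampling caps, centres, and is seeded", {
  rec <- tiny_recording(duration = 30, seed = 3)
  pk <- find_gfp_peaks(gfp(rec))
  m1 <- sample_peak_maps(rec, pk, n_maps = 100, seed = 5)
  expect_equal(dim(m1), c(100, 17))
  expect_lt(max(abs(rowMeans(m1))), 1e-12)
  expect_identical(m1, sample_peak_maps(rec, pk, n_maps = 100, seed = 5))
  expect_message(m2 <- sample_peak_maps(rec, pk[1:50], n_maps = 100, seed = 5),
                 "available")
  expect_equal(nrow(m2), 50)
  expect_error(sample_peak_maps(rec, integer(0), 10), "no GFP peaks")
})

test_that("modified K-means recovers sign-flipped templates exactly", {
  tm <- make_templates(17, 4, seed = 2)
  signs <- rep(c(1, -1), length.out = 40)
  maps <- tm[rep(1:4, each = 10), ] * signs
  ts <- cluster_microstates(maps, k = 4, n_restarts = 10, seed = 1)
  cors <- abs(ts$maps %*% t(tm))
  expect_setequal(unname(apply(cors, 1, which.max)), 1:4)
  expect_equal(unname(apply(cors, 1, max)), rep(1, 4), tolerance = 1e-9)
  expect_gte(ts$gev, max(ts$restart_gev) - 1e-12)   # argmax contract
  expect_true(all(diff(ts$gev_trace) > -1e-12))     # monotone within restart
})

test_that("returned GEV matches an independent re-computation", {
  set.seed(4)
  maps <- matrix(rnorm(30 * 10), 30)
  maps <- maps - rowMeans(maps)
  ts <- cluster_microstates(maps, k = 4, n_restarts = 5, seed = 2)
  # oracle: assign by squared spatial correlation, then GFP-weighted r^2
  r2 <- (stats::cor(t(maps), t(ts$maps)))^2
  a <- max.col(r2, ties.method = "first")
  gfp2 <- rowMeans(maps^2)
  gev_oracle <- sum(gfp2 * r2[cbind(seq_len(30), a)]) / sum(gfp2)
  expect_equal(ts$gev, gev_oracle, tolerance = 1e-10)
  expect_error(cluster_microstates(maps[1:3, ], k = 4), "number of maps")
})

test_that("canonical labelling restores shuffled or sign-flipped references", {
  refs <- canonical_reference_maps(default_channels(17))
  perm <- c(3, 1, 4, 2)
  ts <- template_set(refs[perm, ], labels = paste0("MS", 1:4),
                     channel_names = default_channels(17))
  out <- assign_canonical_labels(ts)
  expect_identical(rownames(out$maps), c("A", "B", "C", "D"))
  expect_equal(unname(abs(diag(out$maps %*% t(refs)))), rep(1, 4), tolerance = 1e-9)
  # sign flips do not change the labelling
  ts2 <- template_set(-refs[perm, ], channel_names = default_channels(17))
  out2 <- assign_canonical_labels(ts2)
  expect_equal(unname(abs(diag(out2$maps %*% t(refs)))), rep(1, 4), tolerance = 1e-9)
  # random templates: output is always a bijective A-D labelling
  for (s in 1:5) {
    tr <- template_set(make_templates(17, 4, seed = 100 + s),
                       channel_names = default_channels(17))
    expect_identical(sort(rownames(assign_canonical_labels(tr)$maps)),
                     c("A", "B", "C", "D"))
  }
})

test_that("backfit labels by squared correlation, polarity-blind", {
  tm <- make_templates(17, 4, seed = 5)
  ts <- template_set(tm, channel_names = default_channels(17))
  one <- labelled_recording(rep(2L, 500), tm)
  one$channel_names <- default_channels(17); rownames(one$data) <- one$channel_names
  seg <- backfit(one, ts)
  expect_equal(nrow(seg$segments), 1)
  expect_equal(unique(seg$labels), 2L)

  labs <- rep(rep(1:2, 5), each = 100)
  rec <- labelled_recording(labs, tm)
  rec$channel_names <- default_channels(17); rownames(rec$data) <- rec$channel_names
  seg2 <- backfit(rec, ts)
  expect_equal(seg2$labels, labs)
  lens <- seg2$segments$end - seg2$segments$start
  expect_true(all(lens == 100))
  par <- compute_parameters(seg2)
  expect_equal(unname(par[c("f1", "f2")]), c(400, 400))  # 100 samples @ 250 Hz

  flip <- rec; flip$data <- -flip$data
  expect_equal(backfit(flip, ts)$labels, seg2$labels)
})

test_that("parameters match hand enumeration and the coverage identity", {
  labs <- c(rep(1L, 50), rep(2L, 50), rep(1L, 50), rep(2L, 100))
  seg <- segmentation(labs, 250, n_classes = 4)
  par <- compute_parameters(seg)
  fn <- attr(par, "feature_names")
  expect_equal(unname(par["f9"]), 0.4)        # coverage A
  expect_equal(unname(par["f5"]), 2.0)        # occurrence A per s
  expect_equal(unname(par["f1"]), 200)        # mean duration A, ms
  expect_equal(unname(par["f13"]), 1.0)       # P(A->B)
  expect_equal(unname(par["f16"]), 1.0)       # P(B->A)
  expect_identical(unname(fn[c("f1", "f13")]),
                   c("mean_duration_ms_A", "p_A>B"))
  expect_equal(sum(par[paste0("f", 9:12)]), 1)

  single <- compute_parameters(segmentation(rep(3L, 100), 250, n_classes = 4))
  expect_equal(unname(single["f11"]), 1)
  expect_true(all(single[paste0("f", 13:24)] == 0))

  # coverage identity on random segmentations: cov = occ * dur(s), exactly
  for (s in 1:5) {
    p <- synth_params(duration = 20, seed = s)
    gt <- simulate_state_sequence(p)
    pp <- compute_parameters(segmentation(gt$state_sequence, 250))
    expect_equal(unname(pp[paste0("f", 9:12)]),
                 unname(pp[paste0("f", 5:8)] * pp[paste0("f", 1:4)] / 1000),
                 tolerance = 1e-12)
  }
  expect_error(segmentation(integer(0), 250), "empty")
})

test_that("the microstate stage is sign- and scale-invariant", {
  rec <- tiny_recording(duration = 10, seed = 13)
  ts <- template_set(make_templates(17, 4, seed = 1),
                     channel_names = rec$channel_names)
  base <- compute_parameters(backfit(rec, ts))
  for (fac in c(-1, 5)) {
    r2 <- rec; r2$data <- fac * r2$data
    expect_equal(compute_parameters(backfit(r2, ts)), base)
  }
})
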