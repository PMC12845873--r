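# Shared fixture builders. Everything is generated in code; no data files.

# A small synthetic recording with stored ground truth attached.
tiny_recording <- function(duration = 10, snr = 4, seed = 11,
                           n_channels = 17, drift = 0.3) {
  p <- synth_params(n_channels = n_channels, duration = duration, snr = snr,
                    drift_amplitude = drift, seed = seed)
  gt <- simulate_state_sequence(p)
  rec <- synthesize_recording(p, gt)
  attr(rec, "truth") <- gt
  rec
}

# Orthonormal k-template set on n channels as a plain matrix.
ortho_templates <- function(n_channels = 8, k = 2, seed = 3) {
  make_templates(n_channels, k, seed = seed)
}

# A recording built directly from a label sequence and templates
# (no carrier, no noise): data[, t] = templates[label_t, ].
labelled_recording <- function(labels, templates, sampling_rate = 250) {
  recording(t(templates[labels, , drop = FALSE]),
            sampling_rate = sampling_rate,
            channel_names = colnames(templates))
}

# Per-subject feature bundles with controlled content, bypassing the
# extraction stage, for fusion/modeling unit tests.
fake_subject <- function(id, group, n_channels = 17, seed = 1) {
  ms <- with_seed_local(seed, stats::rnorm(24))
  names(ms) <- paste0("f", 1:24)
  attr(ms, "feature_names") <- stats::setNames(paste0("ms_", 1:24), names(ms))
  tens <- array(with_seed_local(seed + 1, stats::rnorm(n_channels * 9 * 14)),
                dim = c(n_channels, 9, 14),
                dimnames = list(default_channels(n_channels),
                                paste0("imf", 1:9),
                                names(imf_statistics(c(0, 1)))))
  list(microstate = ms, tensor = tens, subject_id = id, group_label = group)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Separable 2-class feature matrix for classifier tests.
separable_fm <- function(n_per_class = 10, p = 6, gap = 4, seed = 5) {
  X <- with_seed_local(seed, matrix(stats::rnorm(2 * n_per_class * p),
                                    2 * n_per_class, p))
  y <- factor(rep(c("HC", "SCZ"), each = n_per_class), levels = c("HC", "SCZ"))
  X[, 1] <- X[, 1] + gap * (as.integer(y) - 1)
  colnames(X) <- paste0("f", seq_len(p))
  rownames(X) <- sprintf("s%02d", seq_len(nrow(X)))
  structure(list(X = X, y = y, subject_ids = rownames(X),
                 feature_names = colnames(X), mode = "fused"),
            class = "feature_matrix")
}
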