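# Synthetic resting-state EEG with known microstate ground truth.
#
# A cohort is a set of subjects; each subject is a semi-Markov sequence of
# quasi-stable topographies (the "microstates") multiplied by an alpha-band
# carrier, plus a slow additive drift and spatially white + 1/f noise.
# Because the generator stores the state sequence, templates and per-group
# parameter tables, every downstream stage (segmentation, parameter
# estimation, classification, attribution) can be checked against ground
# truth.

#' Default 10-20 channel names
#'
#' The 17-channel montage used for feature extraction (the 19 recorded
#' channels minus the two mastoids `M1`, `M2`).
#'
#' @param n_channels 17 (analysis montage) or 19 (with mastoids appended).
#' @return Character vector of channel names.
#' @export
default_channels <- function(n_channels = 17) {
  base <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
            "C3", "Cz", "C4", "P3", "Pz", "P4", "T5", "T6", "O1", "O2")
  if (n_channels == 17) return(base)
  if (n_channels == 19) return(c(base, "M1", "M2"))
  sprintf("ch%02d", seq_len(n_channels))
}

#' Synthesis parameters
#'
#' Bundles the knobs of the synthetic EEG generator. `duration_mean_ms` and
#' the transition matrix are what distinguish groups in the default cohorts:
#' patients show a raised B-to-D transition probability and a longer class-A
#' mean duration, with a stronger slow drift so that EMD statistics also
#' separate the groups.
#'
#' @param n_channels number of electrodes (default 17).
#' @param sampling_rate sampling rate in Hz (default 250).
#' @param duration recording length per subject in seconds.
#' @param templates a K x n_channels matrix of topographies or `"auto"`.
#' @param duration_mean_ms mean microstate segment duration in ms; scalar or
#'   one value per class.
#' @param transition_matrix K x K row-stochastic matrix, zero diagonal.
#' @param carrier_freq_hz oscillation frequency in Hz (default 10, alpha).
#' @param snr ratio of template-signal power to noise power (default 4).
#' @param drift_amplitude amplitude of the slow additive drift component
#'   relative to unit template norm (default 0.3).
#' @param seed integer seed.
#' @param k number of microstate classes (default 4).
#' @return An object of class `synth_params` (a list).
#' @export
synth_params <- function(n_channels = 17, sampling_rate = 250, duration = 60,
                         templates = "auto", duration_mean_ms = 80,
                         transition_matrix = NULL, carrier_freq_hz = 10,
                         snr = 4, drift_amplitude = 0.3, seed = 1, k = 4) {
  if (is.matrix(templates)) k <- nrow(templates)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (k - 1), k, k)
    diag(transition_matrix) <- 0
  }
  p <- list(n_channels = n_channels, sampling_rate = sampling_rate,
            duration = duration, templates = templates,
            duration_mean_ms = rep_len(duration_mean_ms, k),
            transition_matrix = transition_matrix,
            carrier_freq_hz = carrier_freq_hz, snr = snr,
            drift_amplitude = drift_amplitude, seed = seed, k = k)
  validate_synth_params(p)
  structure(p, class = "synth_params")
}

validate_synth_params <- function(p) {
  tm <- p$transition_matrix
  if (!is.matrix(tm) || nrow(tm) != p$k || ncol(tm) != p$k)
    abort_invalid("transition_matrix must be K x K")
  if (any(abs(diag(tm)) > 1e-12))
    abort_invalid("transition_matrix must have a zero diagonal")
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-8))
    abort_invalid("transition_matrix rows must be nonnegative and sum to 1")
  if (any(p$duration_mean_ms <= 0)) abort_invalid("duration_mean_ms must be > 0")
  if (p$snr <= 0) abort_invalid("snr must be > 0")
  if (p$k < 2) abort_invalid("need at least 2 states")
  invisible(p)
}

#' Generate microstate template topographies
#'
#' Produces `k` zero-mean, unit-norm channel vectors that are mutually
#' orthogonal (hence uncorrelated) in the zero-mean subspace: random Gaussian
#' vectors are centred across channels and then Gram-Schmidt orthogonalised.
#'
#' @param n_channels number of electrodes.
#' @param k number of templates.
#' @param seed integer seed.
#' @return K x n_channels matrix with class labels `LETTERS[1:k]` as rownames.
#' @export
make_templates <- function(n_channels, k, seed = 1) {
  if (!is_count(k) || k < 2) abort_invalid("k must be a count >= 2")
  if (k > n_channels) abort_invalid("k must not exceed n_channels")
  with_seed(seed, {
    maps <- matrix(rnorm(k * n_channels), nrow = k)
    maps <- maps - rowMeans(maps)           # zero-mean across channels
    for (i in seq_len(k)) {                 # Gram-Schmidt in zero-mean subspace
      v <- maps[i, ]
      if (i > 1) for (j in seq_len(i - 1)) v <- v - sum(v * maps[j, ]) * maps[j, ]
      v <- v - mean(v)
      maps[i, ] <- v / sqrt(sum(v^2))
    }
    rownames(maps) <- LETTERS[seq_len(k)]
    colnames(maps) <- default_channels(n_channels)
    maps
  })
}

#' Simulate a semi-Markov microstate state sequence
#'
#' Segment classes follow the requested transition matrix (no
#' self-transitions); segment lengths are gamma-distributed with shape 2 and
#' the requested per-class mean, truncated below at one sample.
#'
#' @param params a [synth_params()] object.
#' @return A `ground_truth` list: `state_sequence` (1-based class index per
#'   sample), `segments` data.frame, `templates` (or `"auto"`), and the
#'   generating parameters.
#' @export
simulate_state_sequence <- function(params) {
  validate_synth_params(params)
  n <- round(params$duration * params$sampling_rate)
  tm <- params$transition_matrix
  if (any(rowSums(tm) == 0)) abort_invalid("degenerate transition row")
  mean_samples <- params$duration_mean_ms / 1000 * params$sampling_rate
  with_seed(params$seed, {
    labels <- integer(n)
    seg_start <- integer(0); seg_class <- integer(0)
    pos <- 1L
    state <- sample.int(params$k, 1L)
    while (pos <= n) {
      # gamma shape 2 => CV = 1/sqrt(2); scale = mean/shape
      len <- max(1L, round(rgamma(1, shape = 2, scale = mean_samples[state] / 2)))
      end <- min(n, pos + len - 1L)
      labels[pos:end] <- state
      seg_start <- c(seg_start, pos); seg_class <- c(seg_class, state)
      pos <- end + 1L
      state <- sample.int(params$k, 1L, prob = tm[state, ])
    }
    structure(list(
      state_sequence = labels,
      segments = data.frame(start = seg_start, class = seg_class),
      templates = params$templates,
      params = params), class = "ground_truth")
  })
}

#' Synthesize one EEG recording from a state sequence
#'
#' `data[ch, t] = template[state_t, ch] * sin(2 pi f t) + drift + noise`.
#' The rectified-sinusoid envelope makes the global field power peak twice
#' per carrier cycle, as in alpha-dominated resting EEG. Noise is spatially
#' white Gaussian plus a per-channel 1/f-shaped component (30% of noise
#' power), jointly scaled so that template-signal power / noise power equals
#' `snr`. The drift is a slow (0.1 Hz) additive component with a fixed
#' random topography, scaled by `drift_amplitude`.
#'
#' @param params a [synth_params()] object.
#' @param truth a `ground_truth` from [simulate_state_sequence()].
#' @param subject_id subject identifier.
#' @param group_label group name.
#' @return A [recording()] object; attribute `components` stores the clean
#'   signal, drift and noise matrices for power audits.
#' @export
synthesize_recording <- function(params, truth, subject_id = "s1",
                                 group_label = "HC") {
  templates <- truth$templates
  if (identical(templates, "auto"))
    templates <- make_templates(params$n_channels, params$k,
                                seed = derive_seed(params$seed, 97))
  if (ncol(templates) != params$n_channels)
    abort_invalid("templates dimension does not match n_channels")
  labels <- truth$state_sequence
  n <- length(labels)
  tvec <- (seq_len(n) - 1) / params$sampling_rate
  carrier <- sin(2 * pi * params$carrier_freq_hz * tvec)
  sig <- t(templates[labels, , drop = FALSE]) * rep(carrier, each = params$n_channels)

  with_seed(derive_seed(params$seed, 131), {
    drift_map <- rnorm(params$n_channels)
    drift_map <- drift_map - mean(drift_map)
    drift_map <- drift_map / sqrt(sum(drift_map^2))
    phase <- runif(1, 0, 2 * pi)
    drift <- params$drift_amplitude * outer(drift_map, sin(2 * pi * 0.1 * tvec + phase))

    white <- matrix(rnorm(params$n_channels * n), params$n_channels, n)
    pink <- t(apply(matrix(rnorm(params$n_channels * n), params$n_channels, n),
                    1, one_over_f))
    # 70% white / 30% 1/f of the noise power, then scale to requested snr
    pink <- pink / sqrt(mean(pink^2))
    white <- white / sqrt(mean(white^2))
    noise <- sqrt(0.7) * white + sqrt(0.3) * pink
    p_sig <- mean(sig^2)
    noise <- noise * sqrt(p_sig / params$snr / mean(noise^2))
  })
  data <- sig + drift + noise
  rec <- recording(data, sampling_rate = params$sampling_rate,
                   channel_names = rownames_or_default(templates, params$n_channels),
                   subject_id = subject_id, group_label = group_label)
  attr(rec, "components") <- list(signal = sig, drift = drift, noise = noise,
                                  templates = templates)
  rec
}

rownames_or_default <- function(templates, n_channels) {
  cn <- colnames(templates)
  if (is.null(cn)) default_channels(n_channels) else cn
}

# 1/f-shaped noise: shape white Gaussian spectrum by 1/sqrt(freq).
one_over_f <- function(x) {
  n <- length(x)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                 # symmetric frequency index
  Re(fft(X / sqrt(f), inverse = TRUE)) / n
}

#' Generate a multi-group synthetic cohort
#'
#' @param group_specs list of lists with elements `params` (a
#'   [synth_params()]), `n_subjects`, `group_label`.
#' @param seed master seed; per-subject seeds are derived deterministically.
#' @return List with `recordings` (list of [recording()]) and `truths`
#'   (matching `ground_truth` objects).
#' @export
generate_cohort <- function(group_specs, seed = 1) {
  if (length(group_specs) < 1) abort_invalid("need at least one group")
  recs <- list(); truths <- list()
  # one shared template set for the whole cohort: microstate topographies
  # are common across subjects, only the dynamics differ by group
  p1 <- group_specs[[1]]$params
  shared <- if (identical(p1$templates, "auto"))
    make_templates(p1$n_channels, p1$k, seed = derive_seed(seed, 9973))
  else p1$templates
  idx <- 0L
  for (g in seq_along(group_specs)) {
    spec <- group_specs[[g]]
    if (!is_count(spec$n_subjects)) abort_invalid("n_subjects must be >= 1")
    for (s in seq_len(spec$n_subjects)) {
      idx <- idx + 1L
      p <- spec$params
      p$seed <- derive_seed(seed, idx)
      truth <- simulate_state_sequence(p)
      truth$templates <- shared
      sid <- sprintf("%s_%02d", spec$group_label, s)
      recs[[idx]] <- synthesize_recording(p, truth, subject_id = sid,
                                          group_label = spec$group_label)
      truths[[idx]] <- truth
    }
  }
  list(recordings = recs, truths = truths)
}

#' Default two-group (HC vs SCZ) cohort specification
#'
#' Encodes the planted group contrast used throughout the test-bench: the
#' patient group has an elevated B-to-D transition probability (0.6 vs the
#' uniform 1/3), a longer class-A mean duration (120 vs 80 ms), and a
#' stronger slow drift (1.0 vs 0.3), mirroring the direction of reported
#' microstate abnormalities in schizophrenia.
#'
#' @param n_per_group subjects per group (default 16).
#' @param duration seconds per subject (default 60).
#' @param snr signal-to-noise power ratio (default 4).
#' @param n_classes 2 (HC vs SCZ) or 3 (HC / severe / mild).
#' @return A list of group specs for [generate_cohort()].
#' @export
default_cohort_spec <- function(n_per_group = 16, duration = 60, snr = 4,
                                n_classes = 2) {
  tm_hc <- matrix(1 / 3, 4, 4); diag(tm_hc) <- 0
  tm_scz <- tm_hc
  tm_scz[2, ] <- c(0.2, 0, 0.2, 0.6)       # B -> D elevated
  hc <- synth_params(duration = duration, snr = snr,
                     duration_mean_ms = c(80, 80, 80, 80),
                     transition_matrix = tm_hc, drift_amplitude = 0.3)
  scz <- synth_params(duration = duration, snr = snr,
                      duration_mean_ms = c(120, 80, 80, 80),
                      transition_matrix = tm_scz, drift_amplitude = 1.0)
  if (n_classes == 2)
    return(list(list(params = hc, n_subjects = n_per_group, group_label = "HC"),
                list(params = scz, n_subjects = n_per_group, group_label = "SCZ")))
  # severity design: severe = stronger contrast, mild = intermediate
  tm_mild <- tm_hc
  tm_mild[2, ] <- c(0.266, 0, 0.267, 0.467)
  mild <- synth_params(duration = duration, snr = snr,
                       duration_mean_ms = c(100, 80, 80, 80),
                       transition_matrix = tm_mild, drift_amplitude = 0.65)
  list(list(params = hc, n_subjects = n_per_group, group_label = "HC"),
       list(params = scz, n_subjects = n_per_group, group_label = "SCZ-BPRS-high"),
       list(params = mild, n_subjects = n_per_group, group_label = "SCZ-BPRS-low"))
}

#' Write a cohort to disk
#'
#' One TSV (or EDF) file per subject plus a tab-separated manifest
#' (`subject_id`, `group_label`, `file`) and a JSON ground-truth file with
#' the per-subject state sequences and generating parameters.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"edf"`.
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("tsv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cohort$recordings), function(i) {
    rec <- cohort$recordings[[i]]
    fn <- file.path(dir, paste0(rec$subject_id, ".", format))
    if (format == "tsv") write_recording_tsv(rec, fn) else write_recording_edf(rec, fn)
    data.frame(subject_id = rec$subject_id, group_label = rec$group_label,
               file = basename(fn))
  })
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  gt <- lapply(cohort$truths, function(tr) list(
    state_sequence = tr$state_sequence,
    duration_mean_ms = tr$params$duration_mean_ms,
    transition_matrix = tr$params$transition_matrix))
  names(gt) <- manifest$subject_id
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"), digits = NA)
  invisible(manifest)
}
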