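# EEG microstate analysis: global field power, GFP-peak topography
# sampling, polarity-invariant modified K-means clustering, per-sample
# backfitting, and the four microstate parameter families.

#' Global field power
#'
#' Per sample n over N electrodes, `GFP_n = sqrt(sum_i (x_in - xbar_n)^2 / N)`
#' — the population standard deviation of the instantaneous potentials
#' across channels.
#'
#' @param rec a [recording()] with at least 2 channels.
#' @return A `gfp_series`: list of `values` (length = sample count) and
#'   `sampling_rate`.
#' @export
gfp <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  x <- rec$data
  if (nrow(x) < 2) abort_invalid("GFP requires at least 2 channels")
  xbar <- colMeans(x)
  v <- sqrt(colMeans((x - rep(xbar, each = nrow(x)))^2))
  structure(list(values = v, sampling_rate = rec$sampling_rate),
            class = "gfp_series")
}

#' Strict local maxima of a GFP series
#'
#' @param g a `gfp_series` (or bare numeric vector) of length >= 3.
#' @return Integer sample indices of strict local maxima (endpoints
#'   excluded).
#' @export
find_gfp_peaks <- function(g) {
  v <- if (inherits(g, "gfp_series")) g$values else g
  if (length(v) < 3) abort_invalid("need at least 3 samples")
  i <- 2:(length(v) - 1)
  i[v[i] > v[i - 1] & v[i] > v[i + 1]]
}

#' Sample GFP-peak topographies
#'
#' Uniformly samples (without replacement) up to `n_maps` peak topographies
#' and centres each across channels. If fewer peaks are available than
#' requested, all are used with a notice.
#'
#' @param rec a [recording()].
#' @param peaks indices from [find_gfp_peaks()].
#' @param n_maps number of maps to draw (default 1000).
#' @param seed integer seed.
#' @return Matrix of sampled maps (rows) x channels.
#' @export
sample_peak_maps <- function(rec, peaks, n_maps = 1000, seed = 1) {
  if (!is_count(n_maps)) abort_invalid("n_maps must be a count >= 1")
  if (length(peaks) == 0) abort_invalid("no GFP peaks available")
  take <- min(n_maps, length(peaks))
  if (take < n_maps)
    notice("only %d GFP peaks available (requested %d)", length(peaks), n_maps)
  sel <- with_seed(seed, sort(sample(peaks, take)))
  maps <- t(rec$data[, sel, drop = FALSE])
  maps <- maps - rowMeans(maps)
  colnames(maps) <- rec$channel_names
  maps
}

#' Construct a template set from given topographies
#'
#' Rows are centred across channels and scaled to unit norm.
#'
#' @param maps K x channels matrix of topographies.
#' @param labels class names (default rownames or `LETTERS`).
#' @param channel_names channel names (default colnames).
#' @return A `template_set`.
#' @export
template_set <- function(maps, labels = NULL,
                         channel_names = colnames(maps)) {
  maps <- as.matrix(maps)
  maps <- maps - rowMeans(maps)
  maps <- maps / sqrt(rowSums(maps^2))
  if (is.null(labels))
    labels <- if (!is.null(rownames(maps))) rownames(maps)
              else LETTERS[seq_len(nrow(maps))]
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(ncol(maps)))
  rownames(maps) <- labels
  colnames(maps) <- channel_names
  structure(list(maps = maps, labels = labels,
                 channel_names = channel_names, gev = NA_real_),
            class = "template_set")
}

# GEV of an assignment: sum over maps of the squared projection onto the
# assigned unit template, normalized by total map power. Maps are zero-mean
# rows, so row power is proportional to squared GFP.
gev_of <- function(maps, templates, assign) {
  proj <- rowSums(maps * templates[assign, , drop = FALSE])
  sum(proj^2) / sum(maps^2)
}

#' Polarity-invariant modified K-means microstate clustering
#'
#' Maps are assigned to the template with maximal squared spatial
#' correlation (sign ignored); each template is re-estimated as the first
#' principal component of its assigned maps. The best of `n_restarts`
#' random initialisations by global explained variance (GEV) is returned.
#'
#' @param maps pooled peak maps (rows) x channels, e.g. from
#'   [sample_peak_maps()] stacked over subjects.
#' @param k number of microstate classes (default 4).
#' @param n_restarts random restarts (default 50).
#' @param max_iter iteration cap per restart (default 300).
#' @param tol convergence tolerance on template change (default 1e-6).
#' @param seed integer seed.
#' @return A `template_set`: `maps` (k x channels, zero-mean unit-norm
#'   rows), `labels`, `channel_names`, `gev`, `restart_gev` (GEV of every
#'   restart), and `gev_trace` (per-iteration GEV of the winning restart).
#' @export
cluster_microstates <- function(maps, k = 4, n_restarts = 50, max_iter = 300,
                                tol = 1e-6, seed = 1) {
  if (!is.matrix(maps)) maps <- as.matrix(maps)
  if (nrow(maps) < k) abort_invalid("k must not exceed the number of maps")
  maps <- maps - rowMeans(maps)
  keep <- rowSums(maps^2) > 1e-24
  maps <- maps[keep, , drop = FALSE]
  best <- NULL
  restart_gev <- numeric(n_restarts)
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- maps[sample.int(nrow(maps), k), , drop = FALSE]
      sol <- mod_kmeans_once(maps, init, max_iter, tol)
      restart_gev[r] <- sol$gev
      if (is.null(best) || sol$gev > best$gev) best <- sol
    }
  })
  cn <- colnames(maps)
  if (is.null(cn)) cn <- sprintf("ch%02d", seq_len(ncol(maps)))
  rownames(best$templates) <- sprintf("MS%d", seq_len(k))
  structure(list(maps = best$templates, labels = rownames(best$templates),
                 channel_names = cn, gev = best$gev,
                 restart_gev = restart_gev, gev_trace = best$trace),
            class = "template_set")
}

mod_kmeans_once <- function(maps, templates, max_iter, tol) {
  templates <- templates / sqrt(rowSums(templates^2))
  trace <- numeric(0)
  assign <- NULL
  for (it in seq_len(max_iter)) {
    proj <- maps %*% t(templates)            # n x k
    assign <- max.col(proj^2, ties.method = "first")
    trace <- c(trace, gev_of(maps, templates, assign))
    new_t <- templates
    for (j in seq_len(nrow(templates))) {
      idx <- which(assign == j)
      if (length(idx) == 0) next             # empty cluster: keep template
      s <- crossprod(maps[idx, , drop = FALSE])
      v <- eigen(s, symmetric = TRUE)$vectors[, 1]
      v <- v - mean(v)
      new_t[j, ] <- v / sqrt(sum(v^2))
    }
    delta <- 1 - abs(rowSums(new_t * templates))
    templates <- new_t
    if (max(delta) < tol) break
  }
  proj <- maps %*% t(templates)
  assign <- max.col(proj^2, ties.method = "first")
  list(templates = templates, assign = assign,
       gev = gev_of(maps, templates, assign), trace = trace)
}

# Approximate canonical microstate topographies on the 10-20 layout:
# A = right-frontal/left-posterior diagonal gradient, B = the mirrored
# diagonal, C = anterior-posterior gradient, D = fronto-central focal map.
# Documented constants used only to order clusters as A-D.
ten_twenty_xy <- function() {
  m <- rbind(
    Fp1 = c(-0.31, 0.95), Fp2 = c(0.31, 0.95), F7 = c(-0.81, 0.59),
    F3 = c(-0.55, 0.67), Fz = c(0, 0.72), F4 = c(0.55, 0.67),
    F8 = c(0.81, 0.59), T3 = c(-0.95, 0), C3 = c(-0.72, 0), Cz = c(0, 0),
    C4 = c(0.72, 0), T4 = c(0.95, 0), T5 = c(-0.81, -0.59),
    P3 = c(-0.55, -0.67), Pz = c(0, -0.72), P4 = c(0.55, -0.67),
    T6 = c(0.81, -0.59), O1 = c(-0.31, -0.95), O2 = c(0.31, -0.95),
    M1 = c(-1.0, -0.25), M2 = c(1.0, -0.25))
  colnames(m) <- c("x", "y")
  m
}

#' Canonical A-D reference maps for a channel set
#'
#' @param channel_names channels that must all be standard 10-20 names.
#' @return 4 x channels matrix (zero-mean unit-norm rows) or NULL if any
#'   channel is unknown.
#' @export
canonical_reference_maps <- function(channel_names) {
  xy <- ten_twenty_xy()
  if (!all(channel_names %in% rownames(xy))) return(NULL)
  x <- xy[channel_names, "x"]; y <- xy[channel_names, "y"]
  refs <- rbind(
    A = (x + y) / sqrt(2),
    B = (-x + y) / sqrt(2),
    C = y,
    D = exp(-((x / 0.6)^2 + ((y - 0.2) / 0.6)^2)))
  refs <- refs - rowMeans(refs)
  refs / sqrt(rowSums(refs^2))
}

#' Order clusters into the canonical A-D classes
#'
#' Greedy one-to-one matching of clusters to the built-in canonical
#' reference maps by maximal absolute spatial correlation (ties broken by
#' listing order). If the channel set is not a standard 10-20 subset, the
#' clusters are ordered by descending per-class explained power instead,
#' with a notice.
#'
#' @param ts a `template_set` with K = 4.
#' @return The `template_set` with rows reordered and labelled A-D.
#' @export
assign_canonical_labels <- function(ts) {
  stopifnot(inherits(ts, "template_set"))
  k <- nrow(ts$maps)
  if (k != 4) abort_invalid("canonical labelling requires K = 4")
  refs <- canonical_reference_maps(ts$channel_names)
  if (is.null(refs)) {
    notice("non-standard channel set; ordering clusters by explained power")
    ord <- seq_len(k)
  } else {
    cors <- abs(refs %*% t(ts$maps))  # 4 refs x k clusters
    ord <- integer(4)
    taken <- rep(FALSE, k)
    pairs <- order(-as.vector(cors))
    for (p in pairs) {
      r <- (p - 1) %% 4 + 1; cl <- (p - 1) %/% 4 + 1
      if (ord[r] == 0 && !taken[cl]) { ord[r] <- cl; taken[cl] <- TRUE }
    }
  }
  ts$maps <- ts$maps[ord, , drop = FALSE]
  rownames(ts$maps) <- LETTERS[1:4]
  ts$labels <- LETTERS[1:4]
  ts
}

#' Backfit: label every sample with its best-matching template
#'
#' Each sample's topography is assigned to the template with maximal
#' squared spatial correlation (polarity ignored). Zero-variance samples
#' inherit the previous sample's class (class 1 at the start); no temporal
#' smoothing is applied.
#'
#' @param rec a [recording()] whose channels match the template set.
#' @param ts a `template_set`.
#' @return A `segmentation`: `labels` (1-based class index per sample),
#'   `segments` data.frame (start, end exclusive, class), `sampling_rate`,
#'   `n_classes`, `class_names`.
#' @export
backfit <- function(rec, ts) {
  stopifnot(inherits(rec, "recording"), inherits(ts, "template_set"))
  if (!identical(rec$channel_names, ts$channel_names))
    abort_invalid("channel sets of recording and templates differ")
  x <- rec$data - rep(colMeans(rec$data), each = nrow(rec$data))
  pw <- colSums(x^2)
  proj <- t(ts$maps %*% x)^2 / pmax(pw, .Machine$double.eps)  # n x k, r^2
  lab <- max.col(proj, ties.method = "first")
  dead <- which(pw <= 1e-24)
  if (length(dead)) {
    notice("%d zero-variance samples inherited the previous label", length(dead))
    for (i in dead) lab[i] <- if (i == 1) 1L else lab[i - 1]
  }
  segmentation(lab, rec$sampling_rate, n_classes = nrow(ts$maps),
               class_names = ts$labels)
}

#' Build a segmentation from a per-sample label vector
#'
#' @param labels integer class indices (1-based), one per sample.
#' @param sampling_rate Hz.
#' @param n_classes number of classes (default `max(labels)`).
#' @param class_names class names (default `LETTERS`).
#' @return A `segmentation` object.
#' @export
segmentation <- function(labels, sampling_rate, n_classes = max(labels),
                         class_names = LETTERS[seq_len(n_classes)]) {
  if (length(labels) == 0) abort_invalid("empty segmentation")
  brk <- c(0L, which(diff(labels) != 0), length(labels))
  segs <- data.frame(start = brk[-length(brk)] + 1L, end = brk[-1] + 1L,
                     class = labels[brk[-length(brk)] + 1L])
  structure(list(labels = labels, segments = segs,
                 sampling_rate = sampling_rate, n_classes = n_classes,
                 class_names = class_names), class = "segmentation")
}

#' The 24 microstate features of a segmentation
#'
#' Per class: mean duration (ms), occurrences (segments per second), time
#' coverage (fraction of samples); plus the 12 ordered transition
#' probabilities `P(i -> j)` between distinct classes. A class with no
#' segments contributes zeros. Naming: f1-f4 mean duration A-D, f5-f8
#' occurrence, f9-f12 coverage, f13-f24 transitions row-major
#' (A>B, A>C, A>D, B>A, ..., D>C).
#'
#' @param seg a [segmentation()].
#' @return Named numeric vector of length `3k + k(k-1)` (24 for k = 4) with
#'   class `microstate_features`; attribute `feature_names` maps f-numbers
#'   to descriptive names.
#' @export
compute_parameters <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  k <- seg$n_classes
  cls <- seg$class_names
  segs <- seg$segments
  total_s <- length(seg$labels) / seg$sampling_rate
  dur <- occ <- cov <- numeric(k)
  for (j in seq_len(k)) {
    sj <- segs[segs$class == j, , drop = FALSE]
    if (nrow(sj) == 0) next
    lens <- sj$end - sj$start
    dur[j] <- mean(lens) * 1000 / seg$sampling_rate
    occ[j] <- nrow(sj) / total_s
    cov[j] <- sum(lens) / length(seg$labels)
  }
  trans <- matrix(0, k, k)
  if (nrow(segs) > 1) {
    from <- segs$class[-nrow(segs)]; to <- segs$class[-1]
    for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1
    rs <- rowSums(trans)
    trans[rs > 0, ] <- trans[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  tp <- numeric(0); tn <- character(0)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    tp <- c(tp, trans[i, j]); tn <- c(tn, paste0("p_", cls[i], ">", cls[j]))
  }
  vals <- c(dur, occ, cov, tp)
  desc <- c(paste0("mean_duration_ms_", cls), paste0("occurrence_per_s_", cls),
            paste0("coverage_", cls), tn)
  names(vals) <- paste0("f", seq_along(vals))
  structure(vals, feature_names = stats::setNames(desc, names(vals)),
            transition_matrix = trans, class = "microstate_features")
}

#' Cohort-level microstate feature extraction
#'
#' Pools randomly sampled GFP-peak maps from every recording, clusters them
#' into `k` group templates, orders the templates canonically, backfits
#' every recording and computes its 24 microstate features.
#'
#' @param recordings list of [recording()] objects.
#' @param n_peaks peak maps sampled per subject (default 1000).
#' @param k number of classes (default 4).
#' @param n_restarts clustering restarts (default 50).
#' @param seed integer seed.
#' @return List: `features` (subjects x 24 matrix), `templates`
#'   (`template_set`), `segmentations` (per subject).
#' @export
microstate_features_cohort <- function(recordings, n_peaks = 1000, k = 4,
                                       n_restarts = 50, seed = 1) {
  pooled <- do.call(rbind, lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    pk <- find_gfp_peaks(gfp(rec))
    sample_peak_maps(rec, pk, n_maps = n_peaks, seed = derive_seed(seed, i))
  }))
  ts <- cluster_microstates(pooled, k = k, n_restarts = n_restarts,
                            seed = derive_seed(seed, 0))
  ts <- if (k == 4) assign_canonical_labels(ts) else ts
  segs <- lapply(recordings, backfit, ts = ts)
  feats <- t(vapply(segs, function(s) as.numeric(compute_parameters(s)),
                    numeric(3 * k + k * (k - 1))))
  colnames(feats) <- names(compute_parameters(segs[[1]]))
  rownames(feats) <- vapply(recordings, function(r) r$subject_id, "")
  list(features = feats, templates = ts, segmentations = segs)
}
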