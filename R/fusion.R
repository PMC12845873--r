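# Feature-level fusion: average the EMD tensor over the IMF axis and
# concatenate with the 24 microstate features into one fused vector per
# subject (24 + N x C = 262 for the 17-channel montage).

#' Average an EMD tensor over the IMF axis
#'
#' `E_avg[i, k] = mean_j e[i, j, k]`, preserving channel and statistic
#' order — an N x C matrix (17 x 14 = 238 values by default).
#'
#' @param tensor an `emd_tensor` from [emd_feature_tensor()].
#' @return N x C matrix with channel rownames and statistic colnames.
#' @export
average_over_imfs <- function(tensor) {
  stopifnot(length(dim(tensor)) == 3)
  apply(tensor, c(1, 3), mean)
}

#' Fuse microstate and averaged EMD features for one subject
#'
#' Concatenates the 24 microstate features with the channel-major flattened
#' N x C averaged EMD block (channel 1's statistics, then channel 2's, ...).
#' Names are `f1..f24` for the microstate block and `f25..` onward for the
#' EMD block; the descriptive name of every slot is kept in the
#' `feature_names` attribute.
#'
#' @param w a `microstate_features` vector (or bare named numeric of the
#'   same layout).
#' @param e an N x C averaged EMD matrix from [average_over_imfs()].
#' @param subject_id,group_label carried through; if both `w` and `e` carry
#'   a `subject_id` attribute and they differ, an error is raised.
#' @return Named numeric vector of length `24 + N*C` with class
#'   `fused_features`.
#' @export
fuse <- function(w, e, subject_id = NULL, group_label = NA_character_) {
  sid_w <- attr(w, "subject_id"); sid_e <- attr(e, "subject_id")
  if (!is.null(sid_w) && !is.null(sid_e) && !identical(sid_w, sid_e))
    abort_invalid("subject ids of the microstate and EMD blocks differ")
  if (is.null(subject_id)) subject_id <- if (!is.null(sid_w)) sid_w else "s1"
  ev <- as.vector(t(e))                       # channel-major
  ch <- rownames(e); st <- colnames(e)
  edesc <- as.vector(t(outer(ch, st, paste, sep = ".")))
  wdesc <- attr(w, "feature_names")
  if (is.null(wdesc)) wdesc <- names(w)
  vals <- c(as.numeric(w), ev)
  names(vals) <- paste0("f", seq_along(vals))
  structure(vals,
            feature_names = stats::setNames(c(unname(wdesc), edesc), names(vals)),
            n_microstate = length(w), subject_id = subject_id,
            group_label = group_label, class = "fused_features")
}

#' Stack per-subject features into a design matrix
#'
#' @param subject_features list with one element per subject, each a list
#'   holding `microstate` (24-vector), `tensor` (`emd_tensor`),
#'   `subject_id`, `group_label`.
#' @param mode `"microstate"` (24 columns), `"emd"` (flattened N x 9 x 14
#'   columns), or `"fused"` (24 + N x C columns).
#' @return A `feature_matrix`: list of `X` (subjects x features, rownames =
#'   subject ids), `y` (factor of group labels), `subject_ids`,
#'   `feature_names` (descriptive), `mode`.
#' @export
build_feature_matrix <- function(subject_features, mode = c("fused", "microstate", "emd")) {
  mode <- match.arg(mode)
  rows <- lapply(subject_features, function(sf) {
    switch(mode,
      microstate = {
        v <- as.numeric(sf$microstate)
        names(v) <- names(sf$microstate)
        attr(v, "desc") <- unname(attr(sf$microstate, "feature_names"))
        v
      },
      emd = {
        t3 <- sf$tensor
        v <- as.vector(aperm(t3, c(3, 2, 1)))   # channel-major, then imf, then stat
        dn <- dimnames(t3)
        g <- expand.grid(stat = dn[[3]], imf = dn[[2]], ch = dn[[1]],
                         stringsAsFactors = FALSE)
        names(v) <- paste0("e", seq_along(v))
        attr(v, "desc") <- paste(g$ch, g$imf, g$stat, sep = ".")
        v
      },
      fused = {
        f <- fuse(sf$microstate, average_over_imfs(sf$tensor),
                  subject_id = sf$subject_id, group_label = sf$group_label)
        v <- as.numeric(f); names(v) <- names(f)
        attr(v, "desc") <- unname(attr(f, "feature_names"))
        v
      })
  })
  lens <- lengths(rows)
  nms <- lapply(rows, names)
  if (length(unique(lens)) != 1 || !all(vapply(nms, identical, TRUE, nms[[1]])))
    abort_invalid("subjects have heterogeneous feature sets")
  X <- do.call(rbind, lapply(rows, as.numeric))
  colnames(X) <- nms[[1]]
  rownames(X) <- vapply(subject_features, function(sf) sf$subject_id, "")
  if (any(!is.finite(X))) abort_invalid("feature matrix contains non-finite values")
  structure(list(X = X,
                 y = factor(vapply(subject_features, function(sf) sf$group_label, "")),
                 subject_ids = rownames(X),
                 feature_names = attr(rows[[1]], "desc"), mode = mode),
            class = "feature_matrix")
}

#' Extract microstate + EMD features for a whole cohort
#'
#' Runs cohort-level microstate analysis (group templates from pooled GFP
#' peaks) and per-subject EMD tensors, returning the per-subject feature
#' bundles that [build_feature_matrix()] consumes.
#'
#' @param recordings list of [recording()] objects.
#' @param n_peaks,k,n_restarts,seed microstate stage parameters.
#' @param m_target IMFs after standardization.
#' @return List: `subjects` (per-subject bundles), `templates`,
#'   `segmentations`.
#' @export
extract_features <- function(recordings, n_peaks = 1000, k = 4,
                             n_restarts = 50, m_target = 9, seed = 1) {
  ms <- microstate_features_cohort(recordings, n_peaks = n_peaks, k = k,
                                   n_restarts = n_restarts, seed = seed)
  subjects <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]
    w <- compute_parameters(ms$segmentations[[i]])
    list(microstate = w, tensor = emd_feature_tensor(rec, m_target = m_target),
         subject_id = rec$subject_id, group_label = rec$group_label)
  })
  list(subjects = subjects, templates = ms$templates,
       segmentations = ms$segmentations)
}
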