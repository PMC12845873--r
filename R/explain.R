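# Exact Shapley attributions for the fitted linear (logistic / softmax)
# classifier. Under feature independence, the Shapley value of feature i
# for a linear margin w'x + b is w_i * (x_i - mu_i) with base value
# w'mu + b at the background mean mu — exact, closed-form, reproducible.

coef_matrix <- function(model, classes) {
  if (length(classes) == 2) {
    b <- coef(model)
    feats <- rownames(b)[-1]
    b <- as.numeric(b)
    # margin of the positive (second) class; the negative class is its mirror
    w <- cbind(-b[-1], b[-1]); b0 <- c(-b[1], b[1])
  } else {
    cl <- coef(model)
    feats <- rownames(cl[[1]])[-1]
    w <- do.call(cbind, lapply(cl, function(m) as.numeric(m)[-1]))
    b0 <- vapply(cl, function(m) as.numeric(m)[1], numeric(1))
  }
  keep <- feats != "..pad.."    # drop the null feature added for 1-column fits
  w <- w[keep, , drop = FALSE]
  colnames(w) <- classes
  list(w = w, b0 = b0)
}

#' Exact linear Shapley attributions
#'
#' @param model a fitted glmnet logistic / multinomial model (from
#'   [fit_predict_logistic()]).
#' @param X samples x features matrix, standardized like the training data,
#'   with the model's feature columns.
#' @param background_mean per-feature background (training mean on the same
#'   scale; zeros for z-scored training data).
#' @param classes class names.
#' @return An `explanation`: `values` (list per class of samples x features
#'   attribution matrices, margin scale), `base` (per class),
#'   `feature_names`, `margins` (reconstructed).
#' @export
linear_shap <- function(model, X, background_mean, classes) {
  cm <- coef_matrix(model, classes)
  if (nrow(cm$w) != ncol(X))
    abort_invalid("feature count of model and X differ")
  if (length(background_mean) != ncol(X))
    abort_invalid("background_mean length does not match the features")
  centred <- sweep(X, 2, background_mean)
  values <- lapply(seq_along(classes), function(ci)
    sweep(centred, 2, cm$w[, ci], "*"))
  names(values) <- classes
  base <- as.numeric(crossprod(cm$w, background_mean)) + cm$b0
  names(base) <- classes
  margins <- matrix(vapply(seq_along(classes), function(ci)
    base[ci] + rowSums(values[[ci]]), numeric(nrow(X))),
    nrow = nrow(X), dimnames = list(rownames(X), classes))
  structure(list(values = values, base = base,
                 feature_names = colnames(X), margins = margins),
            class = "explanation")
}

#' Global feature importance from an explanation
#'
#' Mean absolute attribution per feature for one class, sorted descending
#' (ties broken by feature index).
#'
#' @param exp an `explanation`.
#' @param class_index class position or name.
#' @return data.frame: `feature`, `importance`, `rank`.
#' @export
global_importance <- function(exp, class_index = 1) {
  stopifnot(inherits(exp, "explanation"))
  v <- exp$values[[class_index]]
  imp <- colMeans(abs(v))
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = exp$feature_names[ord], importance = imp[ord],
             rank = seq_along(ord), row.names = NULL)
}

#' Modality share of the attributions
#'
#' Splits global importance into the microstate block (f1-f24) and the EMD
#' block (f25 onward) and normalizes per class.
#'
#' @param exp an `explanation` whose feature names follow the f-numbering.
#' @param n_microstate size of the microstate block (default 24).
#' @return data.frame with one row per class: `microstate_share`,
#'   `emd_share`.
#' @export
report_modality_contribution <- function(exp, n_microstate = 24) {
  fn <- exp$feature_names
  fnum <- suppressWarnings(as.integer(sub("^f", "", fn)))
  is_ms <- !is.na(fnum) & fnum <= n_microstate
  rows <- lapply(names(exp$values), function(cl) {
    imp <- colMeans(abs(exp$values[[cl]]))
    tot <- sum(imp)
    ms <- if (tot > 0) sum(imp[is_ms]) / tot else 0
    data.frame(class = cl, microstate_share = ms,
               emd_share = if (tot > 0) 1 - ms else 0)
  })
  do.call(rbind, rows)
}

#' Pooled held-out-fold explanations for a cross-validation run
#'
#' For every fold of the first CV repetition, attributions of the held-out
#' subjects are computed from that fold's model with the fold's training
#' mean as background (zero on the standardized scale), then pooled.
#'
#' @param cv a `cv_result` from [run_cv()].
#' @param fm the `feature_matrix` the CV was run on.
#' @param repeat_ which repetition to explain (default 1).
#' @return An `explanation` over all subjects (each explained once, by the
#'   fold that held it out).
#' @export
explain_cv <- function(cv, fm, repeat_ = 1) {
  mods <- Filter(function(m) m$repeat_ == repeat_, cv$models)
  classes <- cv$classes
  all_feats <- colnames(fm$X)
  vals <- lapply(classes, function(cl)
    matrix(0, nrow(fm$X), length(all_feats),
           dimnames = list(fm$subject_ids, all_feats)))
  names(vals) <- classes
  base_ps <- matrix(0, nrow(fm$X), length(classes),
                    dimnames = list(fm$subject_ids, classes))
  margins <- base_ps
  for (m in mods) {
    idx <- match(m$test_ids, fm$subject_ids)
    Xs <- sweep(sweep(fm$X[idx, m$selected, drop = FALSE], 2, m$mu), 2,
                m$sd, "/")
    ex <- linear_shap(m$model, Xs, background_mean = rep(0, length(m$selected)),
                      classes = classes)
    for (cl in classes)
      vals[[cl]][idx, m$selected] <- ex$values[[cl]]
    base_ps[idx, ] <- matrix(ex$base, length(idx), length(classes), byrow = TRUE)
    margins[idx, ] <- ex$margins
  }
  base <- colMeans(base_ps); names(base) <- classes
  # each subject's own fold base: base_per_sample + rowSums(values) = margins
  structure(list(values = vals, base = base, feature_names = all_feats,
                 margins = margins, base_per_sample = base_ps),
            class = "explanation")
}

#' Bar chart of global feature importance
#'
#' @param exp an `explanation`.
#' @param class_index class to plot.
#' @param top_n bars to draw (default 20).
#' @return A ggplot object (requires ggplot2).
#' @export
plot_importance <- function(exp, class_index = 1, top_n = 20) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  gi <- head(global_importance(exp, class_index), top_n)
  gi$feature <- factor(gi$feature, levels = rev(gi$feature))
  ggplot2::ggplot(gi, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |attribution| (margin scale)", y = NULL)
}
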