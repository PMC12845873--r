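# Classification: LASSO selection inside subject-wise stratified k-fold
# cross-validation, TPE-tuned (multinomial) logistic regression, and the
# AUC / ACC / SPE / SEN evaluation.

#' Subject-wise stratified k-fold assignment
#'
#' Subjects are shuffled within each class and dealt round-robin into `k`
#' folds, so folds are subject-disjoint and label-stratified.
#'
#' @param subject_ids character vector.
#' @param labels class labels aligned with `subject_ids`.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return Integer fold index per subject (named by subject id).
#' @export
subject_kfold <- function(subject_ids, labels, k = 10, seed = 1) {
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) abort_invalid("subject ids must be unique")
  if (k > n) abort_invalid("k must not exceed the number of subjects")
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)   # stagger classes across folds
    }
  })
  stats::setNames(fold, subject_ids)
}

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- which(sdv > 1e-12)
  if (length(keep) < ncol(X))
    notice("dropped %d constant columns before selection", ncol(X) - length(keep))
  list(mu = mu, sd = sdv, keep = keep)
}

standardize_apply <- function(X, st) {
  Xs <- sweep(sweep(X[, st$keep, drop = FALSE], 2, st$mu[st$keep]), 2,
              st$sd[st$keep], "/")
  Xs
}

default_lambda_grid <- function() exp(seq(log(1e-4), log(1e1), length.out = 30))

#' LASSO feature selection on the squared loss
#'
#' Minimizes `(1/2n) * sum_i (y_i - w'x_i)^2 + lambda * ||w||_1` (no
#' intercept; X is expected column-standardized with training statistics,
#' y numeric-encoded and centred internally). `lambda` is chosen by inner
#' cross-validation over `lambda_grid`; with more than two classes,
#' one-vs-rest runs are pooled and the selected set is the union of the
#' nonzero supports. If every weight shrinks to zero, the single feature
#' with the largest refit coefficient is returned with `fallback = TRUE`.
#'
#' @param X_train standardized design matrix.
#' @param y_train factor or numeric vector.
#' @param lambda_grid candidate penalties (default 30 log-spaced in
#'   `[1e-4, 10]`).
#' @param seed integer seed (inner fold assignment).
#' @param n_inner inner CV folds (default 5).
#' @return A `selection_result`: `lambda`, `weights` (matrix, one column
#'   per one-vs-rest run), `selected` (feature names), `fallback`.
#' @export
lasso_select <- function(X_train, y_train, lambda_grid = default_lambda_grid(),
                         seed = 1, n_inner = 5) {
  if (any(lambda_grid < 0)) abort_invalid("lambda must be >= 0")
  y <- if (is.factor(y_train)) as.integer(y_train) - 1L else as.numeric(y_train)
  classes <- sort(unique(y))
  multiclass <- (is.factor(y_train) && nlevels(y_train) > 2) ||
    (!is.factor(y_train) && length(classes) > 2 && length(classes) <= 10 &&
       all(classes == round(classes)))
  targets <- if (multiclass) lapply(classes, function(cl) as.numeric(y == cl))
             else list(y)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  # at the smallest grid lambdas on p >> n designs the coordinate-descent
  # path may hit maxit; those solutions fall back to the last converged
  # lambda and are practically never selected by the inner CV
  quiet_glmnet <- function(...) withCallingHandlers(
    glmnet::glmnet(...),
    warning = function(w) {
      if (grepl("Convergence for .* lambda", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  n <- nrow(X_train)
  n_inner <- min(n_inner, n)
  foldid <- with_seed(seed, sample(rep_len(seq_len(n_inner), n)))
  weights <- NULL; lambdas <- numeric(0)
  for (yt in targets) {
    yc <- yt - mean(yt)
    cvm <- numeric(length(lambda_grid))
    for (f in seq_len(n_inner)) {
      tr <- foldid != f
      fit <- quiet_glmnet(X_train[tr, , drop = FALSE], yc[tr],
                          family = "gaussian", alpha = 1,
                          lambda = lambda_grid, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-7)
      pred <- predict(fit, X_train[!tr, , drop = FALSE], s = lambda_grid)
      cvm <- cvm + colMeans((yc[!tr] - pred)^2)
    }
    best <- lambda_grid[which.min(cvm)]
    fit <- quiet_glmnet(X_train, yc, family = "gaussian", alpha = 1,
                        lambda = lambda_grid, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-12)
    w <- as.numeric(coef(fit, s = best))[-1]
    weights <- cbind(weights, w)
    lambdas <- c(lambdas, best)
  }
  rownames(weights) <- colnames(X_train)
  selected <- colnames(X_train)[rowSums(abs(weights) > 0) > 0]
  fallback <- FALSE
  if (length(selected) == 0) {
    fallback <- TRUE
    score <- abs(crossprod(X_train, targets[[1]] - mean(targets[[1]])))
    selected <- colnames(X_train)[which.max(score)]
  }
  structure(list(lambda = lambdas, weights = weights, selected = selected,
                 fallback = fallback), class = "selection_result")
}

#' Tune the logistic inverse-regularization strength with TPE
#'
#' A compact seeded Tree-structured Parzen Estimator over `log C` in
#' `[log 1e-3, log 1e3]`: after `n_init` uniform draws, trials are split at
#' the objective's 25% quantile; candidates are sampled from a Gaussian
#' kernel density over the good trials and scored by the good/bad density
#' ratio. The objective is mean inner 3-fold CV accuracy.
#'
#' @param X_train,y_train training design matrix and factor labels.
#' @param search_space list with `logC = c(lower, upper)` (default
#'   `log(1e-3)`..`log(1e3)`).
#' @param budget total objective evaluations (default 50).
#' @param seed integer seed.
#' @param n_init uniform startup trials (default 10).
#' @return List: `best` (list with `C`), `objective`, `trials` data.frame.
#' @export
tune_logistic_tpe <- function(X_train, y_train,
                              search_space = list(logC = log(c(1e-3, 1e3))),
                              budget = 50, seed = 1, n_init = 10) {
  if (!is_count(budget)) abort_invalid("budget must be >= 1")
  if (is.null(search_space$logC)) abort_invalid("empty search space")
  lo <- search_space$logC[1]; hi <- search_space$logC[2]
  y <- as.factor(y_train)
  n <- nrow(X_train)
  k_in <- max(2, min(3, min(table(droplevels(y)))))
  objective <- function(logC) {
    foldid <- subject_kfold(seq_len(n), y, k = k_in, seed = 7)
    acc <- vapply(seq_len(k_in), function(f) {
      tr <- foldid != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      pr <- fit_predict_logistic(X_train[tr, , drop = FALSE], y[tr],
                                 X_train[!tr, , drop = FALSE],
                                 params = list(C = exp(logC)))
      mean(pr$labels == y[!tr])
    }, numeric(1))
    mean(acc, na.rm = TRUE)
  }
  with_seed(seed, {
    xs <- numeric(0); fs <- numeric(0)
    for (t in seq_len(budget)) {
      if (t <= n_init || length(xs) < 4) {
        x <- runif(1, lo, hi)
      } else {
        q <- stats::quantile(fs, 0.75)            # maximize: top 25% are "good"
        good <- xs[fs >= q]; bad <- xs[fs < q]
        if (length(bad) == 0) bad <- xs
        bw <- max((hi - lo) / 20, stats::sd(good), na.rm = TRUE)
        cand <- good[sample.int(length(good), 24, replace = TRUE)] +
          rnorm(24, 0, bw)
        cand <- pmin(pmax(cand, lo), hi)
        dens <- function(pts, centers) vapply(pts, function(p)
          mean(stats::dnorm(p, centers, bw)) + 1e-12, numeric(1))
        x <- cand[which.max(dens(cand, good) / dens(cand, bad))]
      }
      xs <- c(xs, x); fs <- c(fs, objective(x))
    }
    best_i <- which.max(fs)
    list(best = list(C = exp(xs[best_i])), objective = fs[best_i],
         trials = data.frame(logC = xs, objective = fs))
  })
}

#' Fit a (multinomial) logistic model and predict class probabilities
#'
#' Binary labels use the binomial logistic model, three or more classes the
#' multinomial softmax, both as ridge-regularized maximum likelihood
#' (penalty `1/C`).
#'
#' @param X_train,y_train training data (factor labels).
#' @param X_test test design matrix (same columns).
#' @param params list with inverse-regularization `C` (default 1).
#' @return List: `probabilities` (rows sum to 1, columns = class levels),
#'   `labels` (factor), `model` (the fitted glmnet object), `classes`.
#' @export
fit_predict_logistic <- function(X_train, y_train, X_test, params = list(C = 1)) {
  y <- as.factor(y_train)
  if (nlevels(droplevels(y)) < 2) abort_invalid("training data has a single class")
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  if (ncol(X_train) == 1) {     # glmnet needs >= 2 columns; pad with a null feature
    X_train <- cbind(X_train, `..pad..` = 0)
    X_test <- cbind(X_test, `..pad..` = 0)
  }
  lam <- 1 / (params$C * nrow(X_train))
  fit <- withCallingHandlers(
    glmnet::glmnet(X_train, y, family = fam, alpha = 0, lambda = lam,
                   standardize = FALSE, thresh = 1e-10),
    # small training folds are routine here; glmnet's sample-size caution
    # would otherwise flood repeated-CV runs
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pr <- predict(fit, X_test, type = "response")
  if (fam == "binomial") {
    p2 <- cbind(1 - pr[, 1], pr[, 1])
    colnames(p2) <- levels(y)
    pr <- p2
  } else pr <- pr[, , 1]
  pr <- pr / rowSums(pr)
  lab <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                levels = levels(y))
  list(probabilities = pr, labels = lab, model = fit, classes = levels(y))
}

#' Classification metrics and confusion matrix
#'
#' Binary: AUC, accuracy, specificity and sensitivity with the patient
#' (second-level) class as positive. Three or more classes: macro
#' one-vs-rest AUC, macro specificity/sensitivity, overall accuracy.
#'
#' @param y_true factor of true labels.
#' @param probabilities matrix of class probabilities (columns named by
#'   class).
#' @param positive positive class for the binary case (default: second
#'   factor level).
#' @return List: `metrics` (named numeric AUC/ACC/SPE/SEN), `confusion`
#'   (rows = true classes).
#' @export
evaluate <- function(y_true, probabilities, positive = NULL) {
  y_true <- as.factor(y_true)
  cls <- colnames(probabilities)
  pred <- factor(cls[max.col(probabilities, ties.method = "first")], levels = cls)
  cm <- table(true = factor(y_true, levels = cls), predicted = pred)
  acc <- sum(diag(cm)) / sum(cm)
  present <- cls[cls %in% unique(as.character(y_true))]
  if (length(present) < length(cls))
    warning("class(es) absent from y_true excluded from one-vs-rest terms: ",
            paste(setdiff(cls, present), collapse = ","), call. = FALSE)
  if (length(cls) == 2) {
    if (is.null(positive)) positive <- cls[2]
    negative <- setdiff(cls, positive)
    tp <- cm[positive, positive]; fn <- cm[positive, negative]
    tn <- cm[negative, negative]; fp <- cm[negative, positive]
    sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    auc <- if (length(present) == 2)
      as.numeric(pROC::auc(pROC::roc(y_true == positive,
                                     probabilities[, positive],
                                     quiet = TRUE, direction = "<")))
      else NA_real_
  } else {
    per <- lapply(present, function(cl) {
      truth <- y_true == cl
      tp <- sum(truth & pred == cl); fn <- sum(truth & pred != cl)
      tn <- sum(!truth & pred != cl); fp <- sum(!truth & pred == cl)
      auc_cl <- if (length(unique(truth)) == 2)
        as.numeric(pROC::auc(pROC::roc(truth, probabilities[, cl],
                                       quiet = TRUE, direction = "<")))
        else NA_real_
      c(auc = auc_cl, sen = tp / max(tp + fn, 1), spe = tn / max(tn + fp, 1))
    })
    per <- do.call(rbind, per)
    auc <- mean(per[, "auc"], na.rm = TRUE)
    sen <- mean(per[, "sen"]); spe <- mean(per[, "spe"])
  }
  list(metrics = c(AUC = auc, ACC = acc, SPE = spe, SEN = sen), confusion = cm)
}

#' Subject-wise cross-validated classification
#'
#' For each of `n_repeats` seeded repetitions and each of `k` folds:
#' standardize on the training fold, run LASSO selection on the training
#' fold, tune the logistic `C` on the training fold, fit, and predict the
#' held-out subjects. Fold-level metrics are averaged; 95% CIs use the
#' normal approximation `mean +/- 1.96 sd / sqrt(k)` over fold metrics.
#'
#' @param fm a `feature_matrix` from [build_feature_matrix()].
#' @param k folds (default 10).
#' @param n_repeats seeded CV repetitions (default 10).
#' @param seed master seed.
#' @param lambda_grid LASSO penalty grid.
#' @param budget TPE evaluations per fold (default 20).
#' @param positive positive class for binary metrics (default: second
#'   level, i.e. the patient group when HC sorts first).
#' @return A `cv_result`: `fold_metrics` (per repeat x fold), `summary`
#'   (mean and CI per metric), `confusion` (pooled), `folds` (assignments,
#'   first repeat), `selected` (per-fold feature lists), `models` (per
#'   repeat/fold: model, training means/sds, selected features, test ids).
#' @export
run_cv <- function(fm, k = 10, n_repeats = 10, seed = 1,
                   lambda_grid = default_lambda_grid(), budget = 20,
                   positive = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nlevels(fm$y) < 2) abort_invalid("need at least 2 classes")
  fold_rows <- list(); models <- list(); selected <- list()
  conf <- NULL; fold_tab <- NULL
  for (r in seq_len(n_repeats)) {
    fold <- subject_kfold(fm$subject_ids, fm$y, k = k,
                          seed = derive_seed(seed, r))
    if (r == 1) fold_tab <- fold
    for (f in seq_len(k)) {
      tr <- fold != f
      st <- standardize_fit(fm$X[tr, , drop = FALSE])
      Xtr <- standardize_apply(fm$X[tr, , drop = FALSE], st)
      Xte <- standardize_apply(fm$X[!tr, , drop = FALSE], st)
      sel <- lasso_select(Xtr, fm$y[tr], lambda_grid = lambda_grid,
                          seed = derive_seed(seed, r * 1000 + f))
      Xtr_s <- Xtr[, sel$selected, drop = FALSE]
      Xte_s <- Xte[, sel$selected, drop = FALSE]
      tuned <- tune_logistic_tpe(Xtr_s, fm$y[tr], budget = budget,
                                 seed = derive_seed(seed, r * 2000 + f))
      pr <- fit_predict_logistic(Xtr_s, fm$y[tr], Xte_s, params = tuned$best)
      ev <- evaluate(fm$y[!tr], pr$probabilities, positive = positive)
      conf <- if (is.null(conf)) ev$confusion else conf + ev$confusion
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(repeat_ = r, fold = f, t(ev$metrics))
      selected[[length(selected) + 1L]] <- sel$selected
      models[[length(models) + 1L]] <- list(
        repeat_ = r, fold = f, model = pr$model, classes = pr$classes,
        mu = st$mu[st$keep][sel$selected], sd = st$sd[st$keep][sel$selected],
        selected = sel$selected, C = tuned$best$C,
        test_ids = fm$subject_ids[!tr])
    }
  }
  fold_metrics <- do.call(rbind, fold_rows)
  mets <- c("AUC", "ACC", "SPE", "SEN")
  summ <- t(vapply(mets, function(m) {
    v <- fold_metrics[[m]]; v <- v[is.finite(v)]
    ci <- 1.96 * stats::sd(v) / sqrt(k)
    c(mean = mean(v), lo = mean(v) - ci, hi = mean(v) + ci)
  }, numeric(3)))
  structure(list(fold_metrics = fold_metrics, summary = summ,
                 confusion = conf, folds = fold_tab, selected = selected,
                 models = models, mode = fm$mode, classes = levels(fm$y)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> mode=%s, %d fold-evaluations\n", x$mode,
              nrow(x$fold_metrics)))
  print(round(x$summary, 3))
  invisible(x)
}
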