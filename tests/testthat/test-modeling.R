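# Fold assignment, LASSO selection, TPE tuning, logistic fitting, metrics.

test_that("subject folds partition, stratify, and never split a subject", {
  ids <- sprintf("s%02d", 1:20)
  y <- rep(c("HC", "SCZ"), each = 10)
  fold <- subject_kfold(ids, y, k = 10, seed = 3)
  expect_setequal(names(fold), ids)
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) == 2))
  for (f in 1:10) expect_setequal(y[fold == f], c("HC", "SCZ"))
  expect_error(subject_kfold(ids[1:5], y[1:5], k = 10), "exceed")
})

test_that("lasso weights match the closed-form soft-threshold on orthonormal designs", {
  set.seed(1)
  n <- 40; p <- 8
  X <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  colnames(X) <- paste0("x", 1:p)
  beta <- c(3, -2, 1.5, rep(0, p - 3))
  yv <- as.vector(X %*% beta) + rnorm(n, sd = 0.05)
  sel <- lasso_select(X, yv, lambda_grid = c(0.002, 0.01, 0.05), seed = 2)
  lam <- sel$lambda[1]
  yc <- yv - mean(yv)
  cls <- as.vector(crossprod(X, yc))
  oracle <- sign(cls) * pmax(abs(cls) - n * lam, 0)   # minimizer of (1/2n)RSS + lam|w|
  expect_lt(max(abs(as.numeric(sel$weights) - oracle)), 1e-6)
  expect_identical(sel$selected, colnames(X)[oracle != 0])

  # lambda -> infinity: full shrinkage, flagged single-feature fallback
  sel_inf <- lasso_select(X, yv, lambda_grid = c(1e6), seed = 2)
  expect_true(sel_inf$fallback)
  expect_length(sel_inf$selected, 1)

  # lambda ~ 0 on a well-conditioned design recovers least squares
  sel0 <- lasso_select(X, yv, lambda_grid = c(1e-9), seed = 2)
  ols <- as.vector(qr.solve(X, yc))
  expect_lt(max(abs(as.numeric(sel0$weights) - ols)), 1e-6)
})

test_that("multi-class selection unions one-vs-rest supports", {
  set.seed(3)
  X <- scale(matrix(rnorm(45 * 10), 45, 10))
  colnames(X) <- paste0("x", 1:10)
  y <- factor(rep(c("a", "b", "c"), each = 15))
  X[, 1] <- X[, 1] + 3 * (y == "b")
  X[, 5] <- X[, 5] + 3 * (y == "c")
  X <- scale(X)
  sel <- lasso_select(X, y, seed = 4)
  expect_equal(ncol(sel$weights), 3)
  expect_true(all(c("x1", "x5") %in% sel$selected))
})

test_that("TPE tuning is deterministic and honours the argmax contract", {
  fm <- separable_fm(n_per_class = 8)
  one <- tune_logistic_tpe(fm$X, fm$y, budget = 1, seed = 9)
  expect_equal(nrow(one$trials), 1)
  expect_equal(one$objective, one$trials$objective[1])
  tp <- tune_logistic_tpe(fm$X, fm$y, budget = 12, seed = 5)
  expect_gte(tp$objective, max(tp$trials$objective) - 1e-12)
  tp2 <- tune_logistic_tpe(fm$X, fm$y, budget = 12, seed = 5)
  expect_identical(tp$trials, tp2$trials)
  expect_error(tune_logistic_tpe(fm$X, fm$y, search_space = list(), budget = 2),
               "search space")
})

test_that("logistic predictions are calibrated softmax probabilities", {
  fm <- separable_fm(n_per_class = 10, gap = 6)
  tr <- seq(1, 20, by = 2); te <- seq(2, 20, by = 2)
  pr <- fit_predict_logistic(fm$X[tr, ], fm$y[tr], fm$X[te, ],
                             params = list(C = 10))
  expect_equal(unname(rowSums(pr$probabilities)), rep(1, 10), tolerance = 1e-9)
  expect_equal(as.character(pr$labels), as.character(fm$y[te]))
  expect_error(fit_predict_logistic(fm$X[1:5, ], factor(rep("HC", 5)),
                                    fm$X[6:7, ]), "single class")
})

test_that("metrics match hand-computed contingency values", {
  perfect <- cbind(HC = c(1, 1, 0, 0), SCZ = c(0, 0, 1, 1))
  ev <- evaluate(factor(c("HC", "HC", "SCZ", "SCZ")), perfect)
  expect_equal(unname(ev$metrics), c(1, 1, 1, 1))

  # TP=3 FP=1 TN=5 FN=1 -> SEN 0.75, SPE 0.8333, ACC 0.8
  y <- factor(c(rep("SCZ", 4), rep("HC", 6)), levels = c("HC", "SCZ"))
  p_scz <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.2, 0.3, 0.1, 0.2)
  ev2 <- evaluate(y, cbind(HC = 1 - p_scz, SCZ = p_scz))
  expect_equal(unname(ev2$metrics["SEN"]), 0.75)
  expect_equal(unname(ev2$metrics["SPE"]), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(ev2$metrics["ACC"]), 0.8)
  expect_equal(sum(ev2$confusion), 10)

  # random scores: AUC near 1/2 within 3 standard errors
  set.seed(8)
  n <- 2000
  yr <- factor(rep(c("HC", "SCZ"), each = n / 2))
  pr <- runif(n)
  ev3 <- evaluate(yr, cbind(HC = 1 - pr, SCZ = pr))
  se <- sqrt((1 / 12) * (1 / (n / 2) + 1 / (n / 2)))  # conservative AUC SE
  expect_lt(abs(ev3$metrics["AUC"] - 0.5), 3 * se)
})

test_that("permuted labels classify at chance", {
  set.seed(21)
  X <- matrix(rnorm(60 * 5), 60, 5); colnames(X) <- paste0("f", 1:5)
  y <- factor(sample(rep(c("HC", "SCZ"), each = 30)))
  fold <- subject_kfold(as.character(1:60), y, k = 5, seed = 2)
  accs <- vapply(1:5, function(f) {
    pr <- fit_predict_logistic(X[fold != f, ], y[fold != f], X[fold == f, ],
                               list(C = 1))
    mean(pr$labels == y[fold == f])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 1.96 * sqrt(0.25 / 60) + 0.05)
})

test_that("cross-validation never leaks subjects and summarizes all folds", {
  fm <- separable_fm(n_per_class = 8, gap = 5)
  cv <- suppressMessages(run_cv(fm, k = 4, n_repeats = 2, seed = 6, budget = 5))
  expect_equal(nrow(cv$fold_metrics), 8)
  expect_true(all(cv$fold_metrics$AUC >= 0 & cv$fold_metrics$AUC <= 1))
  expect_equal(sum(cv$confusion), 2 * 16)
  # leakage guard: each model's test subjects were never in its training fold
  for (m in cv$models) {
    fold <- subject_kfold(fm$subject_ids, fm$y, k = 4,
                          seed = eegfuse:::derive_seed(6, m$repeat_))
    expect_setequal(m$test_ids, names(fold)[fold == m$fold])
    # standardization statistics derive from the training rows only
    tr_rows <- fm$X[fold != m$fold, m$selected, drop = FALSE]
    expect_equal(unname(m$mu), unname(colMeans(tr_rows)), tolerance = 1e-12)
    expect_equal(unname(m$sd), unname(apply(tr_rows, 2, stats::sd)),
                 tolerance = 1e-12)
  }
  # separable cohort is learnt
  expect_gte(cv$summary["AUC", "mean"], 0.9)
})
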