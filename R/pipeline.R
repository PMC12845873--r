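# Configuration-driven end-to-end pipeline: synthesis/loading ->
# preprocessing -> dual feature extraction -> fusion -> CV modeling ->
# explanation, with per-stage artifacts and a machine-readable summary.

#' Build a pipeline configuration
#'
#' @param output_dir directory for all artifacts.
#' @param seed master seed; every stage derives its own seeds from it.
#' @param input `"synthetic"` or a directory containing per-subject
#'   recordings and a `manifest.tsv` (columns subject_id, group_label,
#'   file).
#' @param modes feature modes to classify with (subset of
#'   `c("microstate","emd","fused")`).
#' @param task `"2-class"` or `"3-class"`.
#' @param n_per_group,duration,snr synthetic cohort size knobs.
#' @param n_peaks,k,n_restarts microstate stage knobs.
#' @param cv_k,n_repeats,budget modeling knobs.
#' @param preprocess apply [filter_resample()] + [rereference_select()]
#'   before feature extraction (default TRUE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, seed = 1, input = "synthetic",
                            modes = c("microstate", "emd", "fused"),
                            task = c("2-class", "3-class"),
                            n_per_group = 16, duration = 60, snr = 4,
                            n_peaks = 1000, k = 4, n_restarts = 50,
                            cv_k = 10, n_repeats = 2, budget = 20,
                            preprocess = TRUE) {
  task <- match.arg(task)
  modes <- match.arg(modes, several.ok = TRUE)
  if (length(modes) == 0) abort_invalid("modes must be nonempty")
  structure(list(output_dir = output_dir, seed = seed, input = input,
                 modes = modes, task = task, n_per_group = n_per_group,
                 duration = duration, snr = snr, n_peaks = n_peaks, k = k,
                 n_restarts = n_restarts, cv_k = cv_k,
                 n_repeats = n_repeats, budget = budget,
                 preprocess = preprocess), class = "pipeline_config")
}

stage_log <- function(stage, t0, ...) {
  notice("stage=%s elapsed=%.1fs %s", stage,
         as.numeric(Sys.time()) - t0, sprintf(...))
}

load_or_simulate <- function(cfg) {
  t0 <- as.numeric(Sys.time())
  if (identical(cfg$input, "synthetic")) {
    spec <- default_cohort_spec(n_per_group = cfg$n_per_group,
                                duration = cfg$duration, snr = cfg$snr,
                                n_classes = if (cfg$task == "2-class") 2 else 3)
    cohort <- generate_cohort(spec, seed = derive_seed(cfg$seed, 1))
    recs <- cohort$recordings
  } else {
    man <- read.table(file.path(cfg$input, "manifest.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
    recs <- lapply(seq_len(nrow(man)), function(i) {
      r <- read_recording(file.path(cfg$input, man$file[i]),
                          group_label = man$group_label[i])
      r$subject_id <- man$subject_id[i]
      r
    })
  }
  stage_log("load", t0, "n_subjects=%d", length(recs))
  recs
}

preprocess_stage <- function(cfg, recs) {
  t0 <- as.numeric(Sys.time())
  recs <- lapply(recs, function(r) {
    r <- filter_resample(r, target_rate = min(250, r$sampling_rate))
    suppressMessages(rereference_select(r))
  })
  stage_log("preprocess", t0, "rate=%g", recs[[1]]$sampling_rate)
  recs
}

#' Run the full pipeline
#'
#' Executes load/simulate, preprocessing, feature extraction, fusion, CV
#' classification per mode and SHAP explanation of the fused model, and
#' writes every stage artifact plus a `summary.json` under
#' `cfg$output_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @return The report list (invisibly also written as JSON): per mode the
#'   AUC/ACC/SPE/SEN summary, the pooled confusion matrices, modality
#'   shares and top features of the fused explanation.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  recs <- load_or_simulate(cfg)
  if (cfg$preprocess) recs <- preprocess_stage(cfg, recs)

  t0 <- as.numeric(Sys.time())
  feats <- extract_features(recs, n_peaks = cfg$n_peaks, k = cfg$k,
                            n_restarts = cfg$n_restarts,
                            seed = derive_seed(cfg$seed, 2))
  stage_log("extract", t0, "n_subjects=%d", length(feats$subjects))

  report <- list(config = unclass(cfg)[setdiff(names(cfg), "output_dir")],
                 modes = list())
  fused_cv <- NULL; fused_fm <- NULL
  for (mode in cfg$modes) {
    t0 <- as.numeric(Sys.time())
    fm <- build_feature_matrix(feats$subjects, mode = mode)
    write_feature_matrix(fm, file.path(cfg$output_dir,
                                       paste0("features_", mode, ".tsv")))
    k_eff <- min(cfg$cv_k, nrow(fm$X))
    if (k_eff < cfg$cv_k)
      notice("reduced CV folds to %d for %d subjects", k_eff, nrow(fm$X))
    cv <- run_cv(fm, k = k_eff, n_repeats = cfg$n_repeats,
                 seed = derive_seed(cfg$seed, 3), budget = cfg$budget)
    utils::write.csv(cv$fold_metrics,
                     file.path(cfg$output_dir, paste0("cv_metrics_", mode, ".csv")),
                     row.names = FALSE)
    report$modes[[mode]] <- list(
      n_features = ncol(fm$X),
      metrics = as.list(stats::setNames(cv$summary[, "mean"],
                                        rownames(cv$summary))),
      ci_lo = as.list(stats::setNames(cv$summary[, "lo"], rownames(cv$summary))),
      ci_hi = as.list(stats::setNames(cv$summary[, "hi"], rownames(cv$summary))),
      confusion = as.data.frame.matrix(cv$confusion))
    if (mode == "fused") { fused_cv <- cv; fused_fm <- fm }
    stage_log(paste0("classify_", mode), t0, "AUC=%.3f",
              cv$summary["AUC", "mean"])
  }
  if (!is.null(fused_cv)) {
    t0 <- as.numeric(Sys.time())
    ex <- explain_cv(fused_cv, fused_fm)
    shares <- report_modality_contribution(ex)
    top <- lapply(names(ex$values), function(cl)
      head(global_importance(ex, cl), 10))
    names(top) <- names(ex$values)
    write_explanation(ex, file.path(cfg$output_dir, "explanation.tsv"))
    report$explanation <- list(modality_shares = shares, top_features = top)
    stage_log("explain", t0, "classes=%d", length(ex$values))
  }
  jsonlite::write_json(report, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Write / read a feature matrix as a delimited table
#'
#' Format: `subject_id`, `group_label`, then one named feature column —
#' the interchange format between extraction and modeling.
#'
#' @param fm a `feature_matrix`.
#' @param path TSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(subject_id = fm$subject_ids,
                   group_label = as.character(fm$y), fm$X,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param mode stored mode tag for the reloaded object.
#' @export
read_feature_matrix <- function(path, mode = "fused") {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(X) <- df$subject_id
  structure(list(X = X, y = factor(df$group_label),
                 subject_ids = df$subject_id,
                 feature_names = colnames(X), mode = mode),
            class = "feature_matrix")
}

write_explanation <- function(ex, path) {
  rows <- do.call(rbind, lapply(names(ex$values), function(cl) {
    gi <- global_importance(ex, cl)
    data.frame(class = cl, gi)
  }))
  write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
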