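# End-to-end experiment: cohort -> hold-out split -> fit feature variants
# A-D -> repeated CV on the training part -> Youden threshold transfer ->
# test-set evaluation -> subgroup stratification; all outputs written as
# CSV/JSON for a reproducible report bundle.

#' Feature sets of the model variants
#'
#' Variant A is the base calculator feature set (age, histology, ER, PR,
#' grade); B adds HER2; C adds Ki67; D adds both.
#'
#' @param variant One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return Character vector of feature names.
#' @export
variant_features <- function(variant) {
  switch(match.arg(variant, c("A", "B", "C", "D")),
         A = base_features(),
         B = c(base_features(), "her2"),
         C = c(base_features(), "ki67"),
         D = c(base_features(), "her2", "ki67"))
}

#' Run the full experiment
#'
#' Orchestrates the whole protocol on one cohort: load (or simulate) the
#' cohort, hold out a test fraction, and for every requested variant fit
#' the model on the full training part, run repeated stratified k-fold
#' cross-validation inside the training part, select the Youden threshold
#' on the full-training-set scores of the refitted model, apply that
#' threshold unchanged to the held-out test set, and tabulate subgroup
#' performance on the test set.  Per variant the bundle directory receives
#' `params_<V>.json`, `cv_<V>.csv`, `test_metrics_<V>.csv` and
#' `stratified_<V>.csv`, plus a `run_log.txt` recording seeds, sizes, class
#' counts and clamped strata.  Outputs contain no timestamps, so two runs
#' of the same configuration are byte-identical.  On error, files created
#' by the failing run are removed.
#'
#' @param config List (or path to a JSON file) with elements:
#'   `cohort` (cohort data frame or CSV path) or `sim`
#'   ([cohort_config()] object; default [default_config()]);
#'   `variants` (subset of A-D, default `"A"`); `split_fraction` (default
#'   0.8); `split_seed`; `cv_rounds`; `cv_folds`; `cv_seed`; `z`;
#'   `min_stratum`; `out_dir` (required).
#' @return Invisibly, a list with per-variant results (`fit`, `cv`,
#'   `threshold`, `test_metrics`, `stratified`) and the split.
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  variants <- config$variants %||% "A"
  split_fraction <- config$split_fraction %||% 0.8
  split_seed <- config$split_seed %||% 1L
  cv_rounds <- config$cv_rounds %||% 100L
  cv_folds <- config$cv_folds %||% 10L
  cv_seed <- config$cv_seed %||% 1L
  z <- config$z %||% 1
  min_stratum <- config$min_stratum %||% 5L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  emit <- function(fun, path) { fun(path); written <<- c(written, path) }
  stage <- "load cohort"
  res <- tryCatch({
    cohort <- if (!is.null(config$cohort)) {
      if (is.character(config$cohort)) read_cohort(config$cohort)
      else validate_cohort(config$cohort)
    } else {
      sim <- config$sim %||% default_config()
      note("simulated cohort: n=%d seed=%d", sim$n, sim$seed)
      generate_cohort(sim)
    }
    note("cohort: n=%d positives=%d", nrow(cohort),
         sum(cohort$node_status))
    stage <- "hold-out split"
    split <- holdout_split(cohort, split_fraction, split_seed)
    note("split: fraction=%g seed=%d train=%d (%d pos) test=%d (%d pos)",
         split_fraction, split_seed,
         nrow(split$train), sum(split$train$node_status),
         nrow(split$test), sum(split$test$node_status))
    results <- list()
    for (v in variants) {
      feats <- variant_features(v)
      stage <- paste("fit variant", v)
      fit <- suppressWarnings(
        sln_fit(split$train, features = feats, z = z,
                min_stratum = min_stratum))
      nclamp <- sum(fit$strata$clamped)
      note("variant %s: features=%s Qn=%.6g clamped=%d",
           v, paste(feats, collapse = "+"), fit$params$qn, nclamp)
      emit(function(p) write_params(fit$params, p),
           file.path(out_dir, sprintf("params_%s.json", v)))
      emit(function(p) {
        df <- fit$strata
        df$rate <- df$observed_rate
        utils::write.csv(
          df[, c("factor", "level", "W", "rate", "g", "clamped")],
          p, row.names = FALSE)
      }, file.path(out_dir, sprintf("fit_report_%s.csv", v)))
      stage <- paste("cross-validation variant", v)
      cv <- repeated_cv(split$train, features = feats, z = z,
                        n_rounds = cv_rounds, n_folds = cv_folds,
                        base_seed = cv_seed, min_stratum = min_stratum)
      emit(function(p) {
        s <- cv$summary
        s$formatted <- sprintf("%.1f (%.1f-%.1f)", 100 * s$median,
                               100 * s$q1, 100 * s$q3)
        utils::write.csv(s, p, row.names = FALSE)
      }, file.path(out_dir, sprintf("cv_%s.csv", v)))
      stage <- paste("threshold selection variant", v)
      train_scores <- predict(fit, split$train)
      thr <- as.numeric(youden_threshold(train_scores,
                                         split$train$node_status))
      note("variant %s: youden threshold on training set = %.6g", v, thr)
      stage <- paste("test evaluation variant", v)
      test_scores <- predict(fit, split$test)
      tm <- evaluate_scores(test_scores, split$test$node_status,
                            threshold = thr)
      emit(function(p) utils::write.csv(
        data.frame(metric = c("auc", "threshold", "accuracy",
                              "sensitivity", "specificity",
                              "tp", "tn", "fp", "fn"),
                   value = c(tm$auc, thr, tm$accuracy, tm$sensitivity,
                             tm$specificity, tm$tp, tm$tn, tm$fp, tm$fn)),
        p, row.names = FALSE),
        file.path(out_dir, sprintf("test_metrics_%s.csv", v)))
      stage <- paste("stratification variant", v)
      strat <- stratified_performance(split$test, test_scores, thr)
      emit(function(p) utils::write.csv(strat, p, row.names = FALSE),
           file.path(out_dir, sprintf("stratified_%s.csv", v)))
      results[[v]] <- list(fit = fit, cv = cv, threshold = thr,
                           test_metrics = tm, stratified = strat)
    }
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(log_lines, log_path)
    written <- c(written, log_path)
    list(results = results, split = split, files = written)
  }, error = function(e) {
    unlink(written)
    stop("experiment failed at stage [", stage, "]: ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
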