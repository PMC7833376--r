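# Performance protocol: ROC/AUC, Youden-index threshold selection,
# confusion metrics, hold-out splitting, repeated stratified k-fold
# cross-validation with median/quartile summaries, subgroup stratification.

.check_scores <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("need both classes present to evaluate")
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the probability that a random positive scores
#' above a random negative, counting ties as one half; identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 outcomes, both classes present.
#' @return AUC as a fraction in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  .check_scores(scores, labels)
  r <- rank(scores, ties.method = "average")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Sensitivity and specificity of the rule "score >= t -> positive" at each
# candidate threshold.
.sens_spec_at <- function(cand, spos, sneg) {
  sens <- vapply(cand, function(t) mean(spos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(sneg < t), numeric(1))
  list(sens = sens, spec = spec)
}

#' Youden-index optimal threshold
#'
#' Maximizes J(t) = sensitivity(t) + specificity(t) - 1 over the candidate
#' set of observed scores, for the classification rule score >= t.  Ties in
#' J are broken toward higher sensitivity, then toward the smaller
#' threshold (a conservative rule for a screening context where false
#' negatives are the costlier error).
#'
#' @inheritParams roc_auc
#' @return The selected threshold, with the achieved J as attribute
#'   `"youden"`.
#' @export
youden_threshold <- function(scores, labels) {
  .check_scores(scores, labels)
  cand <- sort(unique(scores))
  ss <- .sens_spec_at(cand, scores[labels == 1], scores[labels == 0])
  j <- ss$sens + ss$spec - 1
  best <- which(j > max(j) - 1e-12)
  best <- best[ss$sens[best] > max(ss$sens[best]) - 1e-12]
  pick <- best[which.min(cand[best])]
  structure(cand[pick], youden = j[pick])
}

#' Confusion-matrix metrics at a threshold
#'
#' Counts TP/TN/FP/FN for the rule score >= threshold and reports
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP).
#'
#' @inheritParams roc_auc
#' @param threshold Classification cut-off.
#' @return List of class `"sln_metrics"`: `threshold, tp, tn, fp, fn,
#'   accuracy, sensitivity, specificity`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  .check_scores(scores, labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  fp <- sum(pred & labels == 0); tn <- sum(!pred & labels == 0)
  structure(list(threshold = threshold, tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp)),
            class = "sln_metrics")
}

#' @export
print.sln_metrics <- function(x, ...) {
  cat(sprintf("threshold %.4g: TP %d TN %d FP %d FN %d\n",
              x$threshold, x$tp, x$tn, x$fp, x$fn))
  cat(sprintf("accuracy %.4f  sensitivity %.4f  specificity %.4f\n",
              x$accuracy, x$sensitivity, x$specificity))
  if (!is.null(x$auc)) cat(sprintf("AUC %.4f\n", x$auc))
  invisible(x)
}

#' Score a labelled set and summarize performance
#'
#' Convenience wrapper: AUC, Youden threshold (unless one is supplied) and
#' the confusion metrics at that threshold.
#'
#' @inheritParams roc_auc
#' @param threshold Optional fixed threshold; if `NULL` the Youden optimum
#'   is selected on these scores.
#' @return An `"sln_metrics"` list additionally carrying `auc`.
#' @export
evaluate_scores <- function(scores, labels, threshold = NULL) {
  auc <- roc_auc(scores, labels)
  thr <- threshold %||% as.numeric(youden_threshold(scores, labels))
  m <- confusion_metrics(scores, labels, thr)
  m$auc <- auc
  m
}

#' Hold-out train/test split
#'
#' Simple random split without replacement: the training part has
#' `ceiling(fraction * n)` records.  Not class-stratified.
#'
#' @param cohort Cohort data frame.
#' @param fraction Training fraction in (0, 1).
#' @param seed Optional integer seed for reproducibility.
#' @return List with elements `train`, `test` and the training row indices
#'   `idx`.
#' @export
holdout_split <- function(cohort, fraction = 0.8, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(cohort)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, ceiling(fraction * n))
  train <- cohort[idx, , drop = FALSE]
  test <- cohort[-idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  for (part in list(train = train, test = test)) {
    if (length(unique(part$node_status)) < 2L)
      warning("a partition contains a single outcome class; ",
              "downstream fitting will fail")
  }
  list(train = train, test = test, idx = sort(idx))
}

# Class-stratified fold assignment: within each class, shuffle and deal
# fold ids cyclically.
.stratified_folds <- function(labels, n_folds) {
  counts <- table(labels)
  if (min(counts) < n_folds)
    stop("minority class has fewer records (", min(counts),
         ") than folds (", n_folds, "); use fewer folds")
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- sample(which(labels == as.integer(cl)))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs `n_rounds` independent rounds of class-stratified `n_folds`-fold
#' cross-validation of the two-phase model fit.  Per round: records are
#' shuffled under the round seed (`base_seed + round - 1`) and dealt into
#' stratified folds; each fold is scored by a model fitted on the remaining
#' folds; the round's out-of-fold scores are pooled, AUC is computed, the
#' Youden threshold is selected on the pooled scores, and
#' accuracy/sensitivity/specificity follow at that threshold.  Per-metric
#' median and quartiles over rounds use linear interpolation between order
#' statistics.
#'
#' @inheritParams sln_fit
#' @param n_rounds Number of cross-validation rounds.
#' @param n_folds Folds per round (>= 2).
#' @param base_seed Integer; round r uses seed `base_seed + r - 1`.
#' @return Object of class `"sln_cv"`: `rounds` (per-round metrics),
#'   `summary` (median/q1/q3 per metric), `n_rounds`, `n_folds`,
#'   `base_seed`, `features`.
#' @export
repeated_cv <- function(cohort, features = base_features(), z = 1,
                        n_rounds = 100L, n_folds = 10L, base_seed = 1L,
                        age_bins = default_age_bins(), min_stratum = 5L) {
  stopifnot(n_folds >= 2L, n_rounds >= 1L)
  cohort <- validate_cohort(cohort)
  y <- cohort$node_status
  if (length(unique(y)) < 2L) stop("cohort must contain both classes")
  rounds <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    set.seed(base_seed + r - 1L)
    fold <- .stratified_folds(y, n_folds)
    scores <- rep(NA_real_, length(y))
    for (k in seq_len(n_folds)) {
      held <- fold == k
      fit <- suppressWarnings(
        sln_fit(cohort[!held, , drop = FALSE], features = features, z = z,
                age_bins = age_bins, min_stratum = min_stratum))
      scores[held] <- predict(fit, cohort[held, , drop = FALSE])
    }
    stopifnot(!anyNA(scores))   # every record scored exactly once
    m <- evaluate_scores(scores, y)
    rounds[[r]] <- data.frame(round = r, seed = base_seed + r - 1L,
                              auc = m$auc, threshold = m$threshold,
                              accuracy = m$accuracy,
                              sensitivity = m$sensitivity,
                              specificity = m$specificity)
  }
  rounds <- do.call(rbind, rounds)
  summ <- do.call(rbind, lapply(
    c("auc", "accuracy", "sensitivity", "specificity"),
    function(metric) {
      q <- stats::quantile(rounds[[metric]], c(0.25, 0.5, 0.75),
                           type = 7, names = FALSE)
      data.frame(metric = metric, median = q[2], q1 = q[1], q3 = q[3])
    }))
  structure(list(rounds = rounds, summary = summ, n_rounds = n_rounds,
                 n_folds = n_folds, base_seed = base_seed,
                 features = features),
            class = "sln_cv")
}

#' @export
print.sln_cv <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation (base seed %d)\n",
              x$n_rounds, x$n_folds, x$base_seed))
  cat("features:", if (length(x$features))
    paste(x$features, collapse = ", ") else "(none)", "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-11s %.3f (%.3f-%.3f)\n",
                s$metric[i], s$median[i], s$q1[i], s$q3[i]))
  invisible(x)
}

#' Subgroup performance at a fixed threshold
#'
#' Sensitivity and specificity of the rule score >= threshold within
#' clinical subgroups of a scored cohort: overall, tumour-size categories
#' T1 and T2, stratification age classes, grades G1-G3, and the four
#' St. Gallen molecular subtypes.  The threshold is fixed upstream and is
#' not re-optimized per subgroup.  Subgroups without positives report
#' sensitivity `NA`; likewise specificity without negatives.
#'
#' @param cohort Scored cohort data frame.
#' @param scores Numeric scores aligned with `cohort` rows.
#' @param threshold Fixed classification threshold.
#' @param age_bins Stratification age bins (default <=45 / 45-60 / >60).
#' @return Data frame with columns `stratum, n, n_pos, sensitivity,
#'   specificity`.
#' @export
stratified_performance <- function(cohort, scores, threshold,
                                   age_bins = stratification_age_bins()) {
  cohort <- validate_cohort(cohort)
  if (length(scores) != nrow(cohort))
    stop("scores must align with the cohort rows")
  y <- cohort$node_status
  pred <- scores >= threshold
  tc <- t_category(cohort$diameter_mm)
  ac <- .age_level(cohort$age, age_bins)
  st <- assign_subtype(cohort)
  defs <- c(list(Overall = rep(TRUE, nrow(cohort)),
                 T1 = tc == "T1", T2 = tc == "T2"),
            stats::setNames(lapply(age_bins$labels, function(l) ac == l),
                            age_bins$labels),
            list(G1 = cohort$grading == "1", G2 = cohort$grading == "2",
                 G3 = cohort$grading == "3",
                 `Luminal A` = st == "LuminalA",
                 `Luminal B` = st == "LuminalB",
                 `Her2 pos` = st == "HER2pos",
                 `Triple negative` = st == "TripleNegative"))
  out <- do.call(rbind, lapply(names(defs), function(nm) {
    idx <- defs[[nm]]
    npos <- sum(y[idx] == 1); nneg <- sum(y[idx] == 0)
    data.frame(
      stratum = nm, n = sum(idx), n_pos = npos,
      sensitivity = if (npos > 0) sum(pred[idx] & y[idx] == 1) / npos
                    else NA_real_,
      specificity = if (nneg > 0) sum(!pred[idx] & y[idx] == 0) / nneg
                    else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
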