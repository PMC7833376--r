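test_that("AUC matches the Mann-Whitney definition, brute force, and pROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 0, 1)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  expect_error(roc_auc(c(0.1, 0.2), c(1, 0, 1)), "length")
  set.seed(14)
  for (i in 1:25) {
    n <- sample(6:100, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    a <- roc_auc(scores, labels)
    expect_equal(a, brute_auc(scores, labels), tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(exp(3 * scores), labels), a, tolerance = 1e-12)
    # orientation: reversing scores reflects the AUC (ties balance out)
    expect_equal(roc_auc(-scores, labels), 1 - a, tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(15)
    for (i in 1:5) {
      labels <- c(0, 1, rbinom(48, 1, 0.3))
      scores <- round(runif(50), 2)
      a_ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<")))
      expect_equal(roc_auc(scores, labels), a_ref, tolerance = 1e-12)
    }
  }
})

test_that("Youden threshold equals the exhaustive scan with the declared tie-breaks", {
  # worked enumeration: candidates 0.2 .. 0.9
  scores <- c(0.9, 0.7, 0.6, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0)
  b <- brute_youden(scores, labels)
  t_star <- youden_threshold(scores, labels)
  expect_equal(as.numeric(t_star), b$t)
  expect_equal(attr(t_star, "youden"), b$j, tolerance = 1e-12)
  # perfect separation: returns the smallest positive-class score
  expect_equal(as.numeric(youden_threshold(c(0.9, 0.8, 0.2, 0.1),
                                           c(1, 1, 0, 0))), 0.8)
  expect_error(youden_threshold(c(0.3, 0.4), c(1, 1)), "both classes")
  set.seed(22)
  for (i in 1:25) {
    n <- sample(6:100, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.35))
    scores <- round(runif(n), sample(1:3, 1))
    b <- brute_youden(scores, labels)
    t_star <- youden_threshold(scores, labels)
    expect_equal(as.numeric(t_star), b$t)
    expect_equal(attr(t_star, "youden"), b$j, tolerance = 1e-12)
  }
})

test_that("confusion metrics satisfy their identities and a counting oracle", {
  # TP=3 TN=4 FP=1 FN=2 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.3, 0.6, 0.1, 0.2, 0.3, 0.4)
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(scores, labels, 0.5)
  expect_equal(c(m$tp, m$tn, m$fp, m$fn), c(3, 4, 1, 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$tp + m$tn + m$fp + m$fn, length(scores))
  # threshold below all scores classifies everything positive
  low <- confusion_metrics(scores, labels, 0)
  expect_equal(low$sensitivity, 1); expect_equal(low$specificity, 0)
  set.seed(30)
  for (i in 1:20) {
    labels <- c(0, 1, rbinom(48, 1, 0.4))
    scores <- round(runif(50), 2)
    thr <- runif(1)
    m <- confusion_metrics(scores, labels, thr)
    expect_equal(unlist(m[c("tp", "tn", "fp", "fn")]),
                 brute_confusion(scores, labels, thr),
                 ignore_attr = TRUE)
    expect_equal(m$accuracy, (m$tp + m$tn) / 50)
  }
})

test_that("hold-out split has ceiling sizing, is seeded, and partitions the cohort", {
  co <- random_cohort(993, seed = 2)
  sp <- holdout_split(co, 0.8, seed = 10)
  expect_equal(nrow(sp$train), 795L)
  expect_equal(nrow(sp$test), 198L)
  sp2 <- holdout_split(co, 0.8, seed = 10)
  expect_identical(sp$train, sp2$train)
  expect_setequal(c(sp$train$patient_id, sp$test$patient_id),
                  co$patient_id)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_error(holdout_split(co, 1.2), "fraction")
  co$node_status <- c(1L, rep(0L, 992))
  expect_warning(holdout_split(co, 0.8, seed = 1), "single outcome class")
})

test_that("repeated cross-validation is reproducible with coherent summaries", {
  co <- generate_cohort(default_config(n = 600, seed = 55))
  cv <- repeated_cv(co, n_rounds = 3, n_folds = 5, base_seed = 7)
  cv2 <- repeated_cv(co, n_rounds = 3, n_folds = 5, base_seed = 7)
  expect_identical(cv$rounds, cv2$rounds)
  expect_identical(cv$summary, cv2$summary)
  expect_true(all(cv$summary$q1 <= cv$summary$median + 1e-12))
  expect_true(all(cv$summary$median <= cv$summary$q3 + 1e-12))
  expect_equal(cv$rounds$seed, 7:9)
  # a single round's quartiles all equal that round's value
  cv1 <- repeated_cv(co, n_rounds = 1, n_folds = 5, base_seed = 3)
  expect_equal(cv1$summary$q1, cv1$summary$median)
  expect_equal(cv1$summary$q3, cv1$summary$median)
  expect_equal(cv1$summary$median[cv1$summary$metric == "auc"],
               cv1$rounds$auc)
  # minority class smaller than the fold count is refused with advice
  tiny <- co[c(which(co$node_status == 1)[1:3],
               which(co$node_status == 0)[1:60]), ]
  expect_error(repeated_cv(tiny, n_rounds = 1, n_folds = 10), "fewer folds")
})

test_that("subgroup stratification at a fixed threshold matches per-stratum recounting", {
  co <- generate_cohort(default_config(n = 800, seed = 91))
  fit <- suppressWarnings(sln_fit(co))
  scores <- predict(fit)
  thr <- as.numeric(youden_threshold(scores, co$node_status))
  tab <- stratified_performance(co, scores, thr)
  expect_equal(tab$stratum[1], "Overall")
  ov <- confusion_metrics(scores, co$node_status, thr)
  expect_equal(tab$sensitivity[1], ov$sensitivity)
  expect_equal(tab$specificity[1], ov$specificity)
  # brute per-stratum recount for the grade rows
  for (gr in c("1", "2", "3")) {
    idx <- co$grading == gr
    row <- tab[tab$stratum == paste0("G", gr), ]
    expect_equal(row$n, sum(idx))
    if (row$n_pos > 0) {
      cm <- brute_confusion(scores[idx], co$node_status[idx], thr)
      expect_equal(row$sensitivity, cm["tp"] / (cm["tp"] + cm["fn"]),
                   ignore_attr = TRUE)
    }
  }
  # all-correct stratum reports sensitivity and specificity 1
  perfect <- co
  sc2 <- ifelse(perfect$node_status == 1, 0.9, 0.1)
  tab2 <- stratified_performance(perfect, sc2, 0.5)
  expect_true(all(tab2$sensitivity[!is.na(tab2$sensitivity)] == 1))
  expect_true(all(tab2$specificity[!is.na(tab2$specificity)] == 1))
  # empty stratum: size 0 and NA metrics
  no_g1 <- co[co$grading != "1", ]
  tab3 <- stratified_performance(no_g1, scores[co$grading != "1"], thr)
  g1row <- tab3[tab3$stratum == "G1", ]
  expect_equal(g1row$n, 0L)
  expect_true(is.na(g1row$sensitivity) && is.na(g1row$specificity))
})
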