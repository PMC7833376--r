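# Fixture builders and independent brute-force oracles used across tests.

# Independent cohort sampler (deliberately NOT generate_cohort: tests of the
# generator and of fitting need inputs produced by a different code path).
random_cohort <- function(n, seed, prev_link = function(d) plogis(-2 + 0.06 * d)) {
  set.seed(seed)
  d <- pmin(pmax(round(rlnorm(n, 2.6, 0.6), 1), 0.5), 119)
  data.frame(
    patient_id  = sprintf("R%05d", seq_len(n)),
    age         = sample(23:92, n, replace = TRUE),
    diameter_mm = d,
    histology   = sample(c("ductal", "lobular", "unknown"), n, TRUE,
                         prob = c(0.7, 0.1, 0.2)),
    er          = sample(c("pos", "neg"), n, TRUE, prob = c(0.85, 0.15)),
    pr          = sample(c("pos", "neg"), n, TRUE, prob = c(0.75, 0.25)),
    ki67        = sample(c("pos", "neg"), n, TRUE, prob = c(0.35, 0.65)),
    her2        = sample(c("pos", "neg", "unknown"), n, TRUE,
                         prob = c(0.12, 0.87, 0.01)),
    grading     = sample(c("1", "2", "3", "unknown"), n, TRUE,
                         prob = c(0.1, 0.2, 0.1, 0.6)),
    node_status = rbinom(n, 1, prev_link(d)))
}

tiny_cohort <- function() {
  data.frame(
    patient_id  = c("a", "b", "c"),
    age         = c(45L, 56L, 71L),
    diameter_mm = c(12.5, 20, 55),
    histology   = c("ductal", "lobular", "unknown"),
    er          = c("pos", "neg", "pos"),
    pr          = c("pos", "pos", "neg"),
    ki67        = c("neg", "pos", "neg"),
    her2        = c("neg", "pos", "unknown"),
    grading     = c("1", "unknown", "3"),
    node_status = c(0L, 1L, 1L))
}

# Pairwise-count AUC oracle: P(score_pos > score_neg) + 1/2 P(tie).
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Exhaustive Youden scan over observed-score candidates, with the package's
# documented tie-breaks (higher sensitivity, then smaller threshold)
# re-implemented by direct enumeration.
brute_youden <- function(scores, labels) {
  cand <- sort(unique(scores))
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12))
      best <- list(t = t, j = j, sens = sens)
  }
  best
}

# Per-record counting oracle for the confusion matrix.
brute_confusion <- function(scores, labels, threshold) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(scores)) {
    pos <- scores[i] >= threshold
    if (labels[i] == 1) { if (pos) tp <- tp + 1L else fn <- fn + 1L }
    else                { if (pos) fp <- fp + 1L else tn <- tn + 1L }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Fine-grid scan oracle for the moment-matching root
# mean(1 - exp(-q * w)) = target: coarse pass over [0, hi], then a fine pass
# at step `fine` around the coarse optimum.
grid_solve <- function(w, target, hi = NULL, fine = 1e-7) {
  f <- function(q) abs(vapply(q, function(qq) mean(1 - exp(-qq * w)),
                              numeric(1)) - target)
  if (is.null(hi)) {
    hi <- 1 / mean(w)
    while (mean(1 - exp(-hi * w)) < target) hi <- hi * 2
  }
  coarse <- seq(0, hi, length.out = 20001)
  q0 <- coarse[which.min(f(coarse))]
  step <- coarse[2] - coarse[1]
  lo <- max(0, q0 - step)
  fine_grid <- seq(lo, q0 + step, by = fine)
  fine_grid[which.min(f(fine_grid))]
}
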