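# Two-phase moment-matching calibration.
#
# Phase 1: with every g = 1, solve Qn so that the mean predicted probability
# over the training cohort equals the observed positive fraction.
# Phase 2: with Qn fixed, solve each level's g on its stratum so that the
# stratum mean prediction equals the stratum's observed rate; every level is
# fitted independently, against the Phase-1 baseline only.

# Solve mean(1 - exp(-q * w)) = target for q > 0.  The left side is
# continuous and strictly increasing in q from 0 toward 1, so the root is
# unique.  Bracketing interval is expanded geometrically, then Brent's
# method; residual verified against `tol`.
.solve_rate <- function(w, target, tol = 1e-10, max_iter = 200L) {
  stopifnot(length(w) >= 1L, all(w > 0), target > 0, target < 1)
  f <- function(q) mean(-expm1(-q * w)) - target
  hi <- -log1p(-target) / mean(w)
  it <- 0L
  while (f(hi) < 0) {
    hi <- hi * 2
    it <- it + 1L
    if (it > max_iter) stop("failed to bracket the root")
  }
  r <- stats::uniroot(f, c(0, hi), tol = .Machine$double.eps^0.75,
                      maxiter = 1000L)
  q <- r$root
  if (abs(f(q)) > tol) {           # Brent fallback: plain bisection
    lo <- max(0, q - r$estim.prec); hi2 <- q + r$estim.prec
    if (f(lo) > 0 || f(hi2) < 0) { lo <- 0; hi2 <- hi }
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi2) / 2
      if (f(mid) < 0) lo <- mid else hi2 <- mid
      if (abs(f(mid)) <= tol) { q <- mid; break }
    }
    if (abs(f(q)) > tol) stop("root solver did not reach tolerance ", tol)
  }
  q
}

# Clamps for strata whose observed rate is exactly 0 or 1: the model cannot
# produce those rates with finite parameters.
.g_min <- 1e-6
.g_max <- 1e6

#' Phase 1: fit the population parameter Qn
#'
#' Solves `mean(1 - exp(-Qn * D^z)) = ` observed positive fraction over the
#' cohort, with all g = 1, to absolute tolerance 1e-10 on the rate mismatch.
#' The mean prediction is strictly increasing in Qn, so the root is unique.
#'
#' @param cohort Validated cohort with both outcome classes present.
#' @param z Diameter exponent (1 for lymph-node involvement).
#' @return The fitted Qn (positive scalar).
#' @export
fit_qn <- function(cohort, z = 1) {
  cohort <- validate_cohort(cohort)
  prev <- mean(cohort$node_status)
  if (nrow(cohort) == 0L || prev <= 0 || prev >= 1)
    stop("degenerate cohort: need both positive and negative records")
  .solve_rate(cohort$diameter_mm^z, prev)
}

#' Phase 2: fit one level's multiplier g
#'
#' With Qn fixed, solves `mean(1 - exp(-Qn * g * D^z)) = ` the stratum's
#' observed positive rate over the stratum members, to tolerance 1e-10.
#' Each level is fitted independently of every other factor (all other g at
#' 1).  Observed rates of exactly 0 or 1 have no finite root and are clamped
#' to 1e-6 / 1e6 with `clamped = TRUE`.
#'
#' @param stratum List with elements `members` (non-empty cohort data frame
#'   of the records in the level) and optionally `factor`, `level`,
#'   `observed_rate` (recomputed from `members` if absent).
#' @param qn The Phase-1 population parameter.
#' @param z Diameter exponent.
#' @return List with elements `g` (positive scalar) and `clamped` (logical).
#' @export
fit_factor_parameter <- function(stratum, qn, z = 1) {
  members <- stratum$members
  if (is.null(members) || nrow(members) == 0L)
    stop("stratum has no members")
  rate <- stratum$observed_rate %||% mean(members$node_status)
  stopifnot(qn > 0, rate >= 0, rate <= 1)
  if (rate == 0) return(list(g = .g_min, clamped = TRUE))
  if (rate == 1) return(list(g = .g_max, clamped = TRUE))
  list(g = .solve_rate(qn * members$diameter_mm^z, rate), clamped = FALSE)
}

#' Fit the sentinel-node positivity model
#'
#' Runs the full two-phase calibration: Phase 1 fits the population
#' parameter Qn on the whole cohort with all g = 1; Phase 2 fixes Qn and
#' fits each level's multiplier g on the sub-sample of records in that
#' level (size W), one level at a time, treating each prognostic factor as
#' an independent cause.  Levels mapped to `"unknown"` are never fitted and
#' keep the implicit g = 1, as do empty strata and strata smaller than
#' `min_stratum` (reported with a warning).  Strata with an observed rate of
#' exactly 0 or 1 are clamped (see [fit_factor_parameter()]).
#'
#' @param cohort Cohort data frame (validated internally) containing both
#'   outcome classes.
#' @param features Prognostic factors to fit, a subset of [sln_features()];
#'   the default is the base calculator feature set.  May be empty, in which
#'   case predictions depend on diameter alone.
#' @param z Diameter exponent; 1 for lymph-node involvement.
#' @param age_bins Age binning for the `"age"` factor.
#' @param min_stratum Minimum stratum size W fitted; smaller strata keep
#'   g = 1.
#' @return Object of class `"sln_fit"`: `params` (the fitted
#'   [sln_params()]), `strata` (per-level fit report: factor, level, W,
#'   observed_rate, g, clamped, fitted), `n`, `n_pos`, `prevalence`, and the
#'   training `cohort`.
#' @seealso [predict.sln_fit()], [repeated_cv()], [run_experiment()]
#' @examples
#' cohort <- generate_cohort(default_config(n = 400, seed = 7))
#' fit <- sln_fit(cohort)
#' fit
#' head(predict(fit))
#' @export
sln_fit <- function(cohort, features = base_features(), z = 1,
                    age_bins = default_age_bins(), min_stratum = 5L) {
  cohort <- validate_cohort(cohort)
  scheme <- sln_scheme(features, age_bins)
  qn <- fit_qn(cohort, z)
  lv <- map_to_levels(cohort, scheme)
  levs <- factor_levels(scheme)
  g <- lapply(levs, function(l) stats::setNames(rep(1, length(l)), l))
  rows <- list()
  skipped <- character()
  for (f in scheme$features) {
    for (lev in levs[[f]]) {
      idx <- lv[[f]] == lev
      W <- sum(idx)
      rate <- if (W > 0) mean(cohort$node_status[idx]) else NA_real_
      if (W < min_stratum) {
        fitted <- FALSE; clamped <- FALSE; gval <- 1
        skipped <- c(skipped, sprintf("%s:%s (W=%d)", f, lev, W))
      } else {
        res <- fit_factor_parameter(
          list(factor = f, level = lev,
               members = cohort[idx, , drop = FALSE]), qn, z)
        fitted <- TRUE; clamped <- res$clamped; gval <- res$g
      }
      g[[f]][lev] <- gval
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, level = lev, W = W, observed_rate = rate,
        g = gval, clamped = clamped, fitted = fitted)
    }
  }
  if (length(skipped))
    warning("g fixed at 1 for ", length(skipped),
            " stratum/strata below the minimum size: ",
            paste(skipped, collapse = ", "))
  strata <- if (length(rows)) do.call(rbind, rows) else
    data.frame(factor = character(), level = character(), W = integer(),
               observed_rate = numeric(), g = numeric(),
               clamped = logical(), fitted = logical())
  rownames(strata) <- NULL
  structure(list(
    params = sln_params(qn = qn, g = g, z = z, scheme = scheme),
    strata = strata, n = nrow(cohort), n_pos = sum(cohort$node_status),
    prevalence = mean(cohort$node_status), min_stratum = min_stratum,
    cohort = cohort, call = match.call()),
    class = "sln_fit")
}

#' @export
print.sln_fit <- function(x, ...) {
  cat("Sentinel-node positivity model (1 - exp(-Qn * prod(g) * D^Z))\n")
  cat(sprintf("  training records: %d (%d node-positive, prevalence %.4f)\n",
              x$n, x$n_pos, x$prevalence))
  cat(sprintf("  Qn = %.6g, Z = %g\n", x$params$qn, x$params$z))
  feats <- x$params$scheme$features
  cat("  factors:", if (length(feats)) paste(feats, collapse = ", ")
      else "(none - diameter only)", "\n")
  nf <- sum(x$strata$fitted); nc <- sum(x$strata$clamped)
  cat(sprintf("  strata: %d fitted of %d (%d clamped)\n",
              nf, nrow(x$strata), nc))
  invisible(x)
}

#' @export
summary.sln_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.sln_fit")
}

#' @export
print.summary.sln_fit <- function(x, ...) {
  print(x$fit)
  cat("\nPer-stratum calibration report:\n")
  print(x$fit$strata, digits = 4)
  invisible(x)
}

#' @export
coef.sln_fit <- function(object, ...) {
  g <- object$params$g
  out <- c(qn = object$params$qn)
  for (f in names(g))
    out <- c(out, stats::setNames(g[[f]], paste0(f, ":", names(g[[f]]))))
  out
}

#' Predict node-positivity probabilities from a fitted model
#'
#' @param object An [sln_fit()] object.
#' @param newdata Cohort data frame to score; defaults to the training
#'   cohort.
#' @param type `"response"` for probabilities, `"link"` for the exponent
#'   `Qn * prod(g) * D^Z`.
#' @param ... Unused.
#' @return Numeric vector, one value per record, in input order.
#' @export
predict.sln_fit <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  cohort <- validate_cohort(newdata %||% object$cohort)
  eta <- .sln_eta(object$params, cohort)
  if (type == "link") eta else
    .eta_to_prob(eta, cohort$patient_id,
                 allow_saturation = any(object$strata$clamped))
}

#' @export
fitted.sln_fit <- function(object, ...) predict(object)

#' @export
residuals.sln_fit <- function(object, ...) {
  object$cohort$node_status - predict(object)
}

#' Simulate node outcomes from a fitted model
#'
#' Draws Bernoulli node-status outcomes at each record's predicted
#' probability.
#'
#' @param object An [sln_fit()] object.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional integer seed.
#' @param newdata Cohort to simulate for; defaults to the training cohort.
#' @param ... Unused.
#' @return Data frame of `nsim` integer columns.
#' @export
simulate.sln_fit <- function(object, nsim = 1, seed = NULL,
                             newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata)
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot fitted multipliers
#'
#' Dot chart of the fitted per-level multipliers g on a log scale, with a
#' reference line at g = 1 (the value carried by unknown and unfitted
#' levels).
#'
#' @param x An [sln_fit()] object.
#' @param ... Passed to [graphics::dotchart()].
#' @export
plot.sln_fit <- function(x, ...) {
  s <- x$strata[x$strata$fitted & !x$strata$clamped, , drop = FALSE]
  if (nrow(s) == 0L) {
    warning("no fitted, unclamped strata to plot")
    return(invisible(x))
  }
  graphics::dotchart(log(s$g), labels = paste(s$factor, s$level, sep = ":"),
                     xlab = "log(g)  (0 = neutral)", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
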