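test_that("phase 1 matches the closed form on equal-diameter cohorts and rejects degenerate ones", {
  co <- tiny_cohort()[rep(1, 10), ]
  co$patient_id <- sprintf("p%d", 1:10)
  co$diameter_mm <- 10
  co$node_status <- c(1L, 1L, rep(0L, 8))   # prevalence 0.2
  expect_equal(fit_qn(co), -log(0.8) / 10, tolerance = 1e-9)
  co$node_status <- rep(1L, 10)
  expect_error(fit_qn(co), "degenerate")
  co$node_status <- rep(0L, 10)
  expect_error(fit_qn(co), "degenerate")
})

test_that("the root solver agrees with a fine-grid scan", {
  set.seed(42)
  for (i in 1:6) {
    n <- sample(10:50, 1)
    co <- random_cohort(n, seed = 100 + i)
    while (length(unique(co$node_status)) < 2)
      co <- random_cohort(n, seed = 1000 + i)
    q <- fit_qn(co)
    q_grid <- grid_solve(co$diameter_mm, mean(co$node_status))
    expect_lt(abs(q - q_grid), 2e-7)   # fine grid step is 1e-7
  }
  # phase 2 against the same oracle on a larger stratum
  co <- random_cohort(200, seed = 77)
  qn <- 0.018
  g <- fit_factor_parameter(list(members = co), qn)
  expect_false(g$clamped)
  g_grid <- grid_solve(qn * co$diameter_mm, mean(co$node_status))
  expect_lt(abs(g$g - g_grid), 1e-6)
})

test_that("phase 2 has the documented closed forms, fixed point and clamps", {
  qn <- 0.02
  # single-diameter stratum: g = -ln(1-p)/(qn d)
  st <- tiny_cohort()[rep(1, 8), ]
  st$diameter_mm <- 15
  st$node_status <- c(1L, 1L, 1L, rep(0L, 5))
  g <- fit_factor_parameter(list(members = st), qn)
  expect_equal(g$g, -log(1 - 3 / 8) / (qn * 15), tolerance = 1e-9)
  # stratum whose rate equals the phase-1 mean prediction: g = 1
  co <- random_cohort(300, seed = 5)
  qn1 <- fit_qn(co)
  rate0 <- mean(1 - exp(-qn1 * co$diameter_mm))
  g1 <- fit_factor_parameter(list(members = co, observed_rate = rate0), qn1)
  expect_equal(g1$g, 1, tolerance = 1e-8)
  # degenerate rates clamp with a flag
  st0 <- st; st0$node_status <- 0L
  expect_equal(fit_factor_parameter(list(members = st0), qn),
               list(g = 1e-6, clamped = TRUE))
  st1 <- st; st1$node_status <- 1L
  expect_equal(fit_factor_parameter(list(members = st1), qn),
               list(g = 1e6, clamped = TRUE))
  expect_error(fit_factor_parameter(list(members = st[0, ]), qn),
               "no members")
  # a model carrying a clamped rate-1 stratum may saturate at 1 when
  # predicting that stratum's members; an unclamped model may not
  co2 <- random_cohort(120, seed = 61)
  co2$grading <- rep(c("1", "2"), 60)
  co2$node_status[co2$grading == "1"] <- 1L
  co2$node_status[co2$grading == "2"][1:30] <- 0L
  fitc <- suppressWarnings(sln_fit(co2, features = "grading"))
  expect_true(any(fitc$strata$clamped))
  p <- predict(fitc, co2)
  expect_true(all(p[co2$grading == "1"] == 1))
  expect_true(all(p[co2$grading == "2"] < 1))
})

test_that("after the two-phase fit, population and stratum mean predictions match observed rates", {
  co <- random_cohort(600, seed = 12)
  fit <- suppressWarnings(sln_fit(co))
  # phase 1 identity with all g = 1
  prev <- mean(co$node_status)
  expect_lt(abs(mean(1 - exp(-fit$params$qn * co$diameter_mm)) - prev),
            1e-9)
  # phase 2 identity per fitted, unclamped stratum
  lv <- map_to_levels(co, fit$params$scheme)
  s <- fit$strata[fit$strata$fitted & !fit$strata$clamped, ]
  expect_gt(nrow(s), 5)
  for (i in seq_len(nrow(s))) {
    idx <- lv[[s$factor[i]]] == s$level[i]
    pred <- mean(1 - exp(-fit$params$qn * s$g[i] * co$diameter_mm[idx]))
    expect_lt(abs(pred - s$observed_rate[i]), 1e-9)
  }
})

test_that("zero-factor schemes, small strata and fit-report bookkeeping behave as declared", {
  co <- random_cohort(300, seed = 19)
  f0 <- sln_fit(co, features = character())
  expect_equal(nrow(f0$strata), 0L)
  expect_equal(unname(coef(f0)), f0$params$qn)
  co2 <- co; co2$diameter_mm <- 22; co2$patient_id <- paste0("x", 1:300)
  expect_equal(length(unique(predict(f0, co2))), 1L)
  # strata below the minimum size keep g = 1 and are flagged, with a warning
  co$grading <- "2"; co$grading[1:3] <- "1"
  expect_warning(fit <- sln_fit(co, features = "grading"), "minimum size")
  rep1 <- fit$strata[fit$strata$level == "G1", ]
  expect_false(rep1$fitted); expect_equal(rep1$g, 1)
  expect_equal(rep1$W, 3L)
  # every non-unknown level appears exactly once in the report
  full <- suppressWarnings(sln_fit(random_cohort(500, seed = 23),
                                   features = sln_features()))
  key <- paste(full$strata$factor, full$strata$level)
  expect_false(anyDuplicated(key) > 0)
  expect_equal(sort(unique(full$strata$factor)), sort(sln_features()))
})

test_that("model methods expose the fit coherently", {
  co <- random_cohort(400, seed = 44)
  fit <- suppressWarnings(sln_fit(co))
  expect_s3_class(fit, "sln_fit")
  expect_output(print(fit), "Qn")
  expect_output(print(summary(fit)), "calibration report")
  cf <- coef(fit)
  expect_equal(unname(cf["qn"]), fit$params$qn)
  expect_true(all(cf > 0))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), co$node_status - predict(fit))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(400L, 3L))
  expect_true(all(unlist(sim) %in% 0:1))
  expect_identical(sim, simulate(fit, nsim = 3, seed = 1))
})

test_that("a pure-noise factor added to the scheme fits multipliers near 1", {
  cfg <- default_config(n = 12000, seed = 601)
  # outcome law driven by grading only
  g_true <- list(grading = c(G1 = 0.8, G2 = 1.0, G3 = 1.25))
  cfg$true_params <- sln_params(qn = 0.022, g = g_true,
                                scheme = sln_scheme("grading"))
  cfg$grading_probs <- c(G1 = 1 / 3, G2 = 1 / 3, G3 = 1 / 3, unknown = 0)
  co <- generate_cohort(cfg)
  # er carries no true effect; its fitted multipliers must be near 1
  fit <- suppressWarnings(sln_fit(co, features = c("grading", "er")))
  g_er <- fit$strata[fit$strata$factor == "er", "g"]
  expect_true(all(abs(g_er - 1) < 0.1))
})
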