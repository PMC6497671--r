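test_that("the truncated-line basis is anchored at day 0", {
  b <- build_time_spline(c(0, 100, 183, 365), knots = 183)
  expect_equal(unname(b[1, ]), c(0, 0))
  expect_equal(unname(b[2, ]), c(100, 0))
  expect_equal(unname(b[3, ]), c(183, 0))
  expect_equal(unname(b[4, ]), c(183, 182))
  # no knots: a single linear column
  b0 <- build_time_spline(c(0, 50, 400), knots = numeric(0))
  expect_equal(unname(b0[, 1]), c(0, 50, 400))
  # two knots: three bounded segments
  b2 <- build_time_spline(365, knots = c(100, 200), check = FALSE)
  expect_equal(unname(b2[1, ]), c(100, 100, 165))
  expect_warning(build_time_spline(c(0, 100), knots = 183), "outside")
})

test_that("coefficients are recovered exactly on noiseless model data", {
  set.seed(61)
  n <- 60
  days <- c(replicate(n, c(0, sample(90:456, 2))))
  pid <- rep(paste0("P", 1:n), each = 3)
  x <- rnorm(n)[rep(1:n, each = 3)]
  basis <- build_time_spline(days, 183)
  truth <- c(int = 100, t1 = -0.02, t2 = 0.01, x = 3)
  val <- truth["int"] + basis %*% truth[c("t1", "t2")] + truth["x"] * x
  rec <- data.frame(participant_id = pid, value = as.numeric(val), day = days,
                    x = x)
  fit <- suppressMessages(fit_longitudinal(rec, covariate_names = "x"))
  expect_equal(unname(fit$coef[c(".t1", ".t2", "x")]),
               unname(truth[c("t1", "t2", "x")]), tolerance = 1e-6)
  # with zero true random-intercept variance the fixed effects match OLS
  ols <- lm(value ~ .t1 + .t2 + x, data = cbind(rec, basis))
  expect_equal(unname(fit$coef), unname(coef(ols)), tolerance = 1e-6)
  expect_lt(fit$sigma_u2, 1e-8)
})

test_that("rank-deficient designs fail naming the collinear column", {
  rec <- data.frame(participant_id = rep(c("P1", "P2"), each = 3),
                    value = rnorm(6), day = rep(c(0, 100, 300), 2))
  rec$dup <- rec$day  # collinear with the spline for day <= knot
  rec$x <- rnorm(6)
  expect_error(
    suppressWarnings(
      fit_longitudinal(rec, covariate_names = c("x", "dup"), knots = 500)),
    "collinear")
})

test_that("adjusted changes are contrasts of the spline coefficients", {
  sim <- quick_sim(n = 500, trajectory = c(-2.58, -3.26), seed = 62)
  sel <- select_analysis_set(sim$records)
  fit <- fit_longitudinal(sel$records, sim$covariates)
  # manual contrast algebra: 6-month weights (183, 0); 12-month (183, 182)
  est6 <- sum(c(183, 0) * fit$coef[c(".t1", ".t2")])
  a6 <- estimate_adjusted_change(fit, 6)
  expect_equal(a6$estimate, est6)
  a12 <- estimate_adjusted_change(fit, 12)
  expect_equal(a12$estimate,
               sum(c(183, 182) * fit$coef[c(".t1", ".t2")]))
  expect_true(a12$ci_low <= a12$estimate && a12$estimate <= a12$ci_high)
  # truth recovery within the interval on a moderate cohort
  expect_gt(a12$ci_high, -3.26 - 3); expect_lt(a12$ci_low, -3.26 + 3)
  # change at horizon 0 is exactly 0; beyond the data an error
  expect_equal(estimate_adjusted_change(fit, 0)$estimate, 0)
  expect_error(estimate_adjusted_change(fit, 24), "beyond observed range")
})

test_that("population change estimates are unbiased over replicates", {
  # 40 replicates of n=250: mean estimate within 2 Monte-Carlo SEs of truth
  ests <- vapply(1:40, function(i) {
    sim <- quick_sim(n = 250, trajectory = c(-2.58, -3.26), seed = 600 + i)
    sel <- select_analysis_set(sim$records)
    fit <- fit_longitudinal(sel$records, sim$covariates)
    estimate_adjusted_change(fit, 12)$estimate
  }, 0)
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - (-3.26)), 2 * mc_se + 1e-9)
})

test_that("strata interactions recover distinct trajectories and honor the floor", {
  set.seed(63)
  n <- 400
  pid <- paste0("P", 1:n)
  stratum <- rep(c("normal", "high"), c(300, 100))
  days <- t(replicate(n, c(0, sort(sample(90:456, 2)))))
  lat <- rnorm(n, 100, 8)
  extra <- ifelse(stratum == "high", -10, 0)  # extra 12-month decline
  rec <- do.call(rbind, lapply(1:n, function(i) {
    d <- days[i, ]
    data.frame(participant_id = pid[i], value = lat[i] + extra[i] * d / 365 +
                 rnorm(3, 0, 2), day = d,
               stratum = factor(stratum[i], levels = c("normal", "high")))
  }))
  fit <- fit_strata_interaction(rec, min_n = 50, covariate_names = character(0))
  chg_norm <- estimate_adjusted_change(fit, 12)
  chg_high <- estimate_adjusted_change(fit, 12, stratum = "high")
  diff_est <- chg_high$estimate - chg_norm$estimate
  expect_lt(abs(diff_est - (-10)), 2)
  expect_equal(chg_high$n, 100)

  # a 49-participant stratum is dropped with a warning
  rec49 <- rec
  drop_ids <- pid[301:351]  # leave 49 in "high"
  rec49 <- rec49[!rec49$participant_id %in% drop_ids, ]
  w <- testthat::capture_warnings(
    fit_strata_interaction(rec49, min_n = 50, covariate_names = character(0)))
  expect_true(any(grepl("floor", w)))
  # single remaining stratum falls back to the unstratified fit
  solo <- rec[rec$stratum == "normal", ]
  expect_warning(fit_strata_interaction(solo, min_n = 50,
                                        covariate_names = character(0)),
                 "single stratum")
})

test_that("strata with identical truths give null interaction contrasts", {
  # strata assigned independently of the outcome so no regression-to-the-mean
  # leaks into the interaction: the stratum difference must be null-centered
  sim <- quick_sim(n = 800, trajectory = c(-1, -2), seed = 64)
  sel <- select_analysis_set(sim$records)
  set.seed(640)
  strat <- data.frame(participant_id = sel$baselines$participant_id,
                      stratum = sample(c("A", "B"), nrow(sel$baselines), TRUE))
  fit <- fit_strata_interaction(sel$records, strat, sim$covariates, min_n = 50)
  chg <- lapply(names(fit$stratum_n), function(s)
    estimate_adjusted_change(fit, 12,
                             stratum = if (s == names(fit$stratum_n)[1]) NULL
                                       else s))
  diff_ci <- chg[[2]]$estimate - chg[[1]]$estimate
  # contrast of the interaction coefficients directly
  cvec <- c(183, 182)
  nm <- names(fit$coef)
  inter <- fit$coef[grepl("stratumB", nm) & grepl("\\.t", nm)]
  inter <- inter[order(names(inter))]  # .t1 term before .t2 term
  expect_equal(unname(sum(cvec * inter)), diff_ci, tolerance = 1e-8)
  se <- sqrt(sum(outer(cvec, cvec) *
                   fit$vcov[names(inter), names(inter)]))
  expect_lt(abs(diff_ci), 3 * se)
})

test_that("adjusted whole-population change is null-centered under no true change", {
  sim <- quick_sim(n = 1200, trajectory = c(0, 0), seed = 65)
  sel <- select_analysis_set(sim$records)
  fit <- fit_longitudinal(sel$records, sim$covariates)
  a <- estimate_adjusted_change(fit, 12)
  expect_true(a$ci_low <= 0 && 0 <= a$ci_high)
})
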