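test_that("risk windows exclude the exposure day, union and clip", {
  expect_equal(risk_days(10, 15, 183), 11:25)
  expect_equal(risk_days(c(10, 12), 15, 183), 11:27)  # union of windows
  expect_equal(risk_days(180, 15, 183), c(181L, 182L))  # clipped
  expect_equal(risk_days(10, 15, 183, include_exposure_day = TRUE), 10:25)
  expect_equal(risk_days(integer(), 15, 183), integer())
})

test_that("build_case_series reduces exposures to the sufficient summaries", {
  cohort <- data.frame(user_id = c("a", "b", "c"),
                       event_day = c(20L, 5L, 100L),
                       stringsAsFactors = FALSE)
  exposures <- data.frame(user_id = c("a", "a", "c"),
                          day = c(10L, 12L, 150L), stringsAsFactors = FALSE)
  s <- build_case_series(cohort, exposures, W = 15, observation_length = 183)
  expect_equal(s$n_risk_days[s$user_id == "a"], 17L)  # days 11..27
  expect_true(s$event_in_risk[s$user_id == "a"])      # event on day 20
  expect_equal(s$n_risk_days[s$user_id == "b"], 0L)   # unexposed
  expect_false(s$informative[s$user_id == "b"])
  expect_false(s$event_in_risk[s$user_id == "c"])     # event before exposure
  expect_error(build_case_series(cohort[0, ], exposures), "empty cohort")

  # pre-event-only mode discards post-event exposures
  s2 <- build_case_series(cohort, exposures, W = 15, observation_length = 183,
                          pre_event_only = TRUE)
  expect_equal(s2$n_risk_days[s2$user_id == "c"], 0L)
  expect_equal(s2$n_risk_days[s2$user_id == "a"], 17L)
})

test_that("the log-likelihood matches hand evaluation", {
  # one user, D = 10, no exposure: at beta = 0, theta = log(1/10) the
  # contribution is log(1/10) - 1
  s <- case_series(0L, 10L, FALSE, W = 3, observation_length = 10)
  expect_equal(sccs_loglik(s, 0, log(1 / 10)), log(1 / 10) - 1)

  # appending a baseline day (y = 0, r = 0) changes the LL by -exp(theta)
  s11 <- case_series(0L, 11L, FALSE, W = 3, observation_length = 11)
  th <- -0.7
  expect_equal(sccs_loglik(s11, 0.3, th) - sccs_loglik(s, 0.3, th), -exp(th))
})

test_that("the homogeneous design recovers the closed-form MLE", {
  # 100 users, 3 risk / 7 baseline days, 60 events in risk:
  # exp(beta_hat) = (k1 n0) / (k0 n1) = (60 * 7) / (40 * 3) = 3.5
  fit <- sccs(homog_series())
  expect_equal(fit$relative_hazard, 3.5, tolerance = 1e-3)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_null)
  # both optimizers agree
  expect_equal(sccs(homog_series(), method = "optimize")$relative_hazard,
               3.5, tolerance = 1e-3)
})

test_that("event proportions matching day proportions give beta = 0", {
  # k1 / k0 = n1 / n0 solves the score equation at zero
  fit <- sccs(homog_series(n = 100, n_risk = 3, n_base = 7, k_risk = 30))
  expect_equal(fit$coefficients[[1]], 0, tolerance = 1e-6)
  expect_equal(fit$relative_hazard, 1, tolerance = 1e-6)
  expect_equal(fit$p_value, 1, tolerance = 1e-6)
})

test_that("degenerate series hit the cap and are flagged", {
  # single informative user, event outside the risk window: beta -> -Inf
  s <- case_series(3L, 7L, FALSE, W = 3)
  fit <- sccs(s)
  expect_false(fit$converged)
  expect_equal(fit$coefficients[[1]], -10)
  # mirror case
  fit2 <- sccs(case_series(3L, 7L, TRUE, W = 3))
  expect_false(fit2$converged)
  expect_equal(fit2$coefficients[[1]], 10)
  # no informative users at all
  expect_error(sccs(case_series(0L, 10L, FALSE)), "informative")
})

test_that("fit depends only on the per-user sufficient summaries", {
  # two exposure layouts with identical (n_risk, n_baseline, event_in_risk)
  cohort <- data.frame(user_id = sprintf("u%02d", 1:40),
                       event_day = rep(c(15L, 60L), 20),
                       stringsAsFactors = FALSE)
  e1 <- data.frame(user_id = cohort$user_id, day = 10L,
                   stringsAsFactors = FALSE)
  s1 <- build_case_series(cohort, e1, W = 10, observation_length = 183)
  s2 <- case_series(s1$n_risk_days, s1$n_baseline_days, s1$event_in_risk,
                    W = 10, observation_length = 183)
  expect_equal(sccs(s1)$coefficients, sccs(s2)$coefficients)

  # invariance to user order
  s3 <- s1[rev(seq_len(nrow(s1))), ]
  attributes(s3)[c("W", "observation_length", "class")] <-
    attributes(s1)[c("W", "observation_length", "class")]
  expect_equal(sccs(s3)$coefficients, sccs(s1)$coefficients)
})

test_that("profile fit equals the joint simplex oracle on small series", {
  set.seed(31)
  for (r in 1:6) {
    n <- sample(5:50, 1)
    s <- simulate_case_series(n_users = n, relative_hazard = exp(runif(1, -1, 1.5)),
                              W = sample(5:20, 1), observation_length = 60,
                              seed = 2000 + r)
    fp <- sccs(s)
    if (!fp$converged) next
    fj <- sccs_joint(s)
    expect_lt(abs(fp$coefficients[[1]] - fj$beta_hat), 1e-3)
  }
  # the closed-form example through the joint route
  fj <- sccs_joint(homog_series(n = 30, k_risk = 18))
  expect_equal(fj$relative_hazard, (18 * 7) / (12 * 3), tolerance = 1e-3)
})

test_that("model methods behave like a standard fit object", {
  fit <- sccs(homog_series())
  expect_named(coef(fit), "log_relative_hazard")
  expect_equal(unname(exp(coef(fit))), fit$relative_hazard, tolerance = 1e-9)
  ci <- confint(fit)
  expect_lt(ci[1, 1], coef(fit)[[1]]); expect_gt(ci[1, 2], coef(fit)[[1]])
  expect_equal(dim(vcov(fit)), c(1L, 1L))
  expect_s3_class(summary(fit), "summary.sccs")
  expect_output(print(fit), "relative hazard")
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
})

test_that("planted relative hazards are recovered from simulated series", {
  set.seed(99)
  betas <- vapply(1:10, function(r) {
    s <- simulate_case_series(n_users = 800, relative_hazard = 3, W = 15,
                              seed = 4000 + r)
    sccs(s)$coefficients[[1]]
  }, 0)
  expect_lt(abs(mean(betas) - log(3)), 0.1)
})
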