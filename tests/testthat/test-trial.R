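# Trial evaluation, correlations, importances.

test_that("arm assignment splits as evenly as possible, reproducibly", {
  arms <- assign_arms(seq_len(495), seed = 23)
  expect_length(arms$control, 247)
  expect_length(arms$intervention, 248)
  expect_setequal(c(arms$control, arms$intervention), 1:495)

  arms2 <- assign_arms(seq_len(495), seed = 23)
  expect_identical(arms, arms2)

  two <- assign_arms(c("a", "b"), seed = 1)
  expect_length(two$control, 1)
  expect_error(assign_arms("a"), "at least 2")

  df <- data.frame(id = 1:10)
  armsdf <- assign_arms(df, seed = 2)
  expect_equal(nrow(armsdf$control), 5)
})

test_that("trial effect reports rates, reduction and a p-value", {
  # arms engineered to the published whole-cohort rates
  control <- rep(c(1L, 0L), c(42, 158))        # 21.0%
  intervention <- rep(c(1L, 0L), c(214, 1786)) # 10.7%
  tr <- trial_effect(control, intervention)
  expect_equal(tr$noshow_rate_control, 0.21)
  expect_equal(tr$noshow_rate_intervention, 0.107)
  expect_equal(tr$reduction_pp, 10.3)
  expect_lt(tr$p_value, 0.01)

  same <- trial_effect(rep(c(1L, 0L), 50), rep(c(1L, 0L), 50))
  expect_equal(same$reduction_pp, 0)
  expect_gt(same$p_value, 0.99)

  expect_error(trial_effect(integer(0), c(1L)), "nonempty")

  fi <- trial_effect(control, intervention, test = "fisher")
  ch <- trial_effect(control, intervention, test = "chisq")
  expect_lt(fi$p_value, 0.01)
  expect_equal(ch$p_value, tr$p_value, tolerance = 0.5)
})

test_that("arms of 247/248 at rates 0.21/0.107 are usually significant", {
  set.seed(29)
  pvals <- replicate(1000, {
    trial_effect(rbinom(247, 1, 0.21), rbinom(248, 1, 0.107))$p_value
  })
  expect_lt(median(pvals), 0.01)
})

test_that("trial rates convert to the cost-effectiveness metrics", {
  ce <- trial_to_ce(0.210, 0.107, n_contacted = 247, n_total = 4617,
                    digits = 2)
  expect_equal(ce$P_R, 0.49)
  expect_equal(ce$P_C, 0.05)
  expect_equal(ce$m1, 9.8)
  expect_equal(round(ce$m2, 2), 0.47)
  expect_equal(ce$reduction_pp, 10.3)

  none <- trial_to_ce(0.2, 0.2, 0, 100)
  expect_equal(none$P_R, 0)
  expect_true(is.na(none$m1))
  expect_warning(und <- trial_to_ce(0, 0, 10, 100), "undefined")
  expect_true(is.na(und$P_R))
})

test_that("simulated reminders convert no-shows at the given rate", {
  out <- rep(1L, 4000)
  conv <- simulate_intervention(out, conversion = 0.7, seed = 31)
  expect_lt(abs(mean(conv) - 0.3), 0.03)
  expect_identical(simulate_intervention(out, 0.7, seed = 31), conv)
  shows <- rep(0L, 100)
  expect_identical(simulate_intervention(shows, 0.9, seed = 1), shows)
})

test_that("feature correlations recover exact and synthetic structure", {
  y <- rep(c(1L, 0L), 50)
  x <- cbind(same = as.numeric(y), opposite = 1 - y, flat = 1,
             noise = runif(100))
  fc <- feature_correlations(x, y)
  expect_equal(fc$r[fc$feature == "same"], 1)
  expect_equal(fc$r[fc$feature == "opposite"], -1)
  expect_true(is.na(fc$r[fc$feature == "flat"]))
  expect_equal(fc$feature[1:2], c("same", "opposite"))
  expect_lt(fc$p_value[1], 1e-10)

  expect_error(feature_correlations(cbind(a = rep(1, 10)),
                                    rep(c(0L, 1L), 5)), "constant")
})

test_that("correlation table on synthetic data shows the dominant signs", {
  s <- default_schedule()
  enc <- encode_features(s, delay = "binned")
  fc <- feature_correlations(enc$x, enc$y)
  r_hist <- fc$r[fc$feature == "hist_noshow"]
  r_d0 <- fc$r[fc$feature == "delay_weeks=w0"]
  expect_gt(r_hist, 0)
  expect_lt(r_d0, 0)
  expect_lt(fc$p_value[fc$feature == "hist_noshow"], 0.001)
  expect_lt(fc$p_value[fc$feature == "delay_weeks=w0"], 0.001)
})

test_that("Gini importances are a normalized descending ranking", {
  set.seed(33)
  n <- 2000
  x <- cbind(signal = runif(n), noise1 = runif(n), noise2 = runif(n),
             noise3 = runif(n))
  y <- rbinom(n, 1, plogis(5 * x[, "signal"] - 3))
  clf <- fit_classifier("random_forest", x, y,
                        list(n_estimators = 100), seed = 1)
  gi <- gini_importances(clf)
  expect_equal(sum(gi$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(gi$importance) <= 0))
  expect_equal(gi$feature[1], "signal")

  # rpart-based ensemble importances behave the same way
  clf2 <- fit_classifier("balanced_bagging", x, y,
                         list(n_estimators = 10), seed = 1)
  gi2 <- gini_importances(clf2)
  expect_equal(sum(gi2$importance), 1, tolerance = 1e-9)
  expect_equal(gi2$feature[1], "signal")

  lr <- fit_classifier("logistic_regression", x, y, seed = 1)
  expect_error(gini_importances(lr), "tree-based")
})
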