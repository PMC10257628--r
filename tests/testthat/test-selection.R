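# Split, grid search, threshold tuning, best-model selection.

test_that("the stratified split preserves prevalence and is reproducible", {
  s <- default_schedule()
  sp <- names(which.max(table(s$specialty)))
  one <- s[s$specialty == sp, ][1:1000, ]
  res <- split_train_test(one, fraction = 0.8, seed = 17)
  expect_equal(nrow(res$train) + nrow(res$test), 1000)
  expect_equal(nrow(res$train), 800, tolerance = 2)
  expect_lt(abs(mean(res$train$outcome) - mean(one$outcome)), 0.01)
  expect_length(intersect(res$train$appointment_id,
                          res$test$appointment_id), 0)

  res2 <- split_train_test(one, fraction = 0.8, seed = 17)
  expect_identical(res$train$appointment_id, res2$train$appointment_id)
})

test_that("tiny or single-class specialties are skipped with a warning", {
  s <- default_schedule()
  sp <- unique(s$specialty)[1:2]
  small <- rbind(s[s$specialty == sp[1], ][1:5, ],
                 s[s$specialty == sp[2], ][1:100, ])
  expect_warning(res <- split_train_test(small, seed = 1), "skipped")
  expect_equal(res$skipped, sp[1])
  expect_false(sp[1] %in% res$train$specialty)
})

test_that("stratified folds balance the classes", {
  y <- rep(c(0L, 1L), c(80, 20))
  f <- stratified_folds(y, 5, seed = 2)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.integer(table(f[y == 1L])), rep(4L, 5))
  expect_identical(f, stratified_folds(y, 5, seed = 2))
})

test_that("grid search returns the single point of a singleton grid", {
  set.seed(8)
  x <- cbind(a = runif(200), b = runif(200))
  y <- rbinom(200, 1, plogis(3 * x[, 1] - 2))
  gs <- grid_search(x, y, "logistic_regression",
                    list(penalty = "l2", C = 1), k = 3, seed = 1)
  expect_equal(gs$best_params, list(penalty = "l2", C = 1))
  expect_true(is.finite(gs$best_m2))
  expect_length(gs$oof, length(y))
})

test_that("grid search prefers trees deep enough for an interaction", {
  # sign-flipping interaction: the effect of b reverses with a, so an
  # additive ensemble of stumps underfits while depth-2 trees capture it
  set.seed(9)
  n <- 800
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.3)
  p <- ifelse(a == b, 0.15, 0.9)
  y <- rbinom(n, 1, p)
  x <- cbind(a = a, b = b, noise = runif(n))
  gs <- grid_search(x, y, "adaboost",
                    list(max_depth = c(1, 2), min_samples_leaf = 2,
                         n_estimators = 30, learning_rate = 0.5),
                    k = 3, seed = 2)
  expect_equal(gs$best_params$max_depth, 2)
  res <- gs$results
  expect_gt(res$m2[2], res$m2[1])
})

test_that("threshold tuning matches brute force and breaks ties low", {
  # probabilities equal to the labels: every t in (0, 1] is optimal,
  # the tie rule picks the lowest grid point
  y <- rep(c(1L, 0L), c(30, 70))
  tt <- tune_threshold(as.numeric(y), y, objective = "m2")
  expect_equal(tt$threshold, 0.01)
  expect_false(tt$degenerate)

  # constant scorer is flagged
  tt2 <- tune_threshold(rep(0.5, 100), y, objective = "m2")
  expect_true(tt2$degenerate)

  expect_error(tune_threshold(runif(5), rep(0L, 5), objective = "m1"),
               "undefined at every threshold")
})

test_that("P_C is non-increasing in the threshold for any fixed scorer", {
  set.seed(10)
  probs <- runif(300)
  y <- rbinom(300, 1, probs)
  pcs <- vapply(seq(0, 1, 0.05), function(t) {
    proportion_actions(confusion_counts(y, as.integer(probs >= t)))
  }, numeric(1))
  expect_true(all(diff(pcs) <= 0))
})

test_that("selection picks the better finalist and reports CV metrics", {
  set.seed(11)
  n <- 500
  x <- cbind(signal = runif(n), noise = runif(n))
  y <- rbinom(n, 1, plogis(4 * x[, 1] - 3))
  finalists <- list(
    list(algorithm = "logistic_regression",
         params = list(penalty = "l2", C = 1), threshold = 0.3),
    list(algorithm = "balanced_bagging",
         params = list(n_estimators = 10), threshold = 0.5)
  )
  sel <- select_best(x, y, finalists, k = 5, seed = 3)
  expect_s3_class(sel$classifier, "noshow_classifier")
  expect_equal(nrow(sel$report), 2)
  expect_equal(sel$report$cv_m1[sel$winner],
               max(sel$report$cv_m1, na.rm = TRUE))
  # an informative feature exists: the winner clearly beats chance
  expect_gt(sel$report$cv_auc[sel$winner], 0.6)

  one <- select_best(x, y, finalists[1], k = 5, seed = 3)
  expect_equal(one$winner, 1)
})
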