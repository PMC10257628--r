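# Cost-effectiveness metric layer.

test_that("confusion counts cross-tabulate exactly", {
  cc <- confusion_counts(rep(0, 10), rep(0, 10))
  expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), c(0, 0, 0, 10))

  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(c(cc$TP, cc$FP, cc$FN, cc$TN), c(1, 1, 1, 1))

  # flagging everyone: FP = number of shows, TP = number of no-shows
  truth <- c(1, 0, 0, 1, 0)
  cc <- confusion_counts(truth, rep(1, 5))
  expect_equal(cc$TP, 2)
  expect_equal(cc$FP, 3)

  expect_error(confusion_counts(integer(0), integer(0)), "empty")
  expect_error(confusion_counts(c(1, 0), 1), "length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
})

test_that("P_C, NSP and P_R follow their defining arithmetic", {
  cc <- as_confusion_counts(TP = 18, FP = 9, FN = 2, TN = 71)
  expect_equal(proportion_actions(cc), 0.27)
  expect_equal(noshow_rates(cc), c(NSP_i = 0.20, NSP_f = 0.02))
  expect_equal(reduction(cc), 0.9)

  # the published trial arithmetic: 247 flagged of 4,617 rounds to 0.05
  cc <- as_confusion_counts(TP = 200, FP = 47, FN = 770, TN = 3600)
  expect_equal(cc$N, 4617)
  expect_equal(round(proportion_actions(cc), 2), 0.05)

  expect_equal(reduction(as_confusion_counts(1, 0, 3, 0)), 0.25)
  expect_equal(reduction(as_confusion_counts(5, 2, 0, 3)), 1)
  expect_warning(r <- reduction(as_confusion_counts(0, 2, 0, 8)),
                 "undefined")
  expect_true(is.na(r))
})

test_that("m1 and m2 match their closed forms", {
  expect_equal(m1_from_rates(p_r = 0.05, p_c = 0.01), 5)
  expect_equal(m1_from_rates(p_r = 0.49, p_c = 0.05), 9.8)
  expect_equal(m2_from_rates(p_r = 0.49, p_c = 0.05), 0.4655)

  # perfect classifier at prevalence pi: m1 = 1/pi, m2 = 1 - pi
  for (pi in c(0.1, 0.2, 0.5)) {
    n <- 100
    truth <- rep(c(1, 0), c(pi * n, (1 - pi) * n))
    cc <- confusion_counts(truth, truth)
    expect_equal(metric_m1(cc), 1 / pi)
    expect_equal(metric_m2(cc), 1 - pi)
  }

  expect_warning(m1 <- metric_m1(as_confusion_counts(0, 0, 4, 6)),
                 "P_C = 0")
  expect_true(is.na(m1))
})

test_that("the reduction identity and metric bounds hold on random counts", {
  set.seed(101)
  for (i in 1:200) {
    cells <- rpois(4, lambda = sample(c(1, 5, 50), 4, replace = TRUE))
    cc <- as_confusion_counts(cells[1], cells[2], cells[3], cells[4])
    if (cc$N == 0) next
    rates <- noshow_rates(cc)
    expect_lte(rates["NSP_f"], rates["NSP_i"])
    if (cc$TP + cc$FN >= 1) {
      p_r <- reduction(cc)
      # TP/(FN+TP) == 1 - FN/(FN+TP) == 1 - NSP_f/NSP_i
      expect_equal(p_r, 1 - cc$FN / (cc$FN + cc$TP))
      expect_equal(p_r, 1 - rates[["NSP_f"]] / rates[["NSP_i"]])
      m2 <- metric_m2(cc)
      expect_gte(m2, 0)
      expect_lte(m2, 1)
      m1 <- suppressWarnings(metric_m1(cc))
      if (!is.na(m1)) expect_gte(m1, p_r)  # since P_C <= 1
    }
  }
})

test_that("projected post-intervention rate applies (1 - P_R) * NSP_i", {
  expect_equal(project_noshow_rate(0.20, 0.49), 0.102)
  expect_equal(project_noshow_rate(0.20, 0), 0.20)
  expect_equal(project_noshow_rate(0.20, 1), 0)
})

test_that("GM and MCC behave on canonical cases", {
  perfect <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(geometric_mean(perfect), 1)
  expect_equal(matthews_corr(perfect), 1)

  cc <- as_confusion_counts(TP = 1, FP = 1, FN = 1, TN = 1)
  expect_equal(geometric_mean(cc), 0.5)
  expect_equal(matthews_corr(cc), 0)

  # label-independent predictions with balanced margins: MCC near 0
  set.seed(3)
  truth <- rep(c(0, 1), 500)
  pred <- sample(truth)
  expect_lt(abs(matthews_corr(confusion_counts(truth, pred))), 0.1)

  expect_warning(g <- geometric_mean(as_confusion_counts(0, 2, 0, 8)),
                 "degenerate")
  expect_equal(g, 0)
})

test_that("rank-based AUC matches the concordance count and pROC", {
  expect_equal(auc_score(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc_score(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1)

  set.seed(4)
  probs <- runif(300)
  truth <- rbinom(300, 1, 0.25)
  expect_lt(abs(auc_score(probs, truth) - 0.5), 0.12)

  if (requireNamespace("pROC", quietly = TRUE)) {
    probs <- runif(200)
    truth <- rbinom(200, 1, plogis(3 * probs - 2))
    ref <- as.numeric(pROC::auc(pROC::roc(truth, probs, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_score(probs, truth), ref)
  }
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "both classes")
})
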