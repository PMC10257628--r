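# Deployment ranking and the top-k call policy.

fitted_small <- function() {
  if (!exists("small_fit", envir = .schedule_cache)) {
    s <- cached_schedule("rank600",
                         sim_config(n_patients = 600, n_specialties = 2,
                                    seed = 19))
    f <- noshow_fit(s, roster = "logistic_regression", seed = 4)
    assign("small_fit", list(s = s, f = f), envir = .schedule_cache)
  }
  get("small_fit", envir = .schedule_cache)
}

test_that("ranking sorts by probability and flags at the threshold", {
  fs <- fitted_small()
  rl <- rank_appointments(fs$f, fs$s)
  expect_s3_class(rl, "ranked_list")
  expect_equal(rl$rank, seq_len(nrow(rl)))
  expect_true(all(diff(rl$probability) <= 0))
  thr <- vapply(fs$f$models, `[[`, numeric(1), "threshold")
  expect_equal(rl$flagged,
               as.integer(rl$probability >= thr[rl$specialty]))
})

test_that("ranking is invariant to input row order", {
  fs <- fitted_small()
  rl <- rank_appointments(fs$f, fs$s)
  set.seed(20)
  shuffled <- fs$s[sample(nrow(fs$s)), ]
  rl2 <- rank_appointments(fs$f, shuffled)
  rownames(rl) <- rownames(rl2) <- NULL
  attr(rl, "skipped") <- attr(rl2, "skipped") <- NULL
  expect_equal(rl2, rl)
})

test_that("unmodelled specialties are reported, not crashed on", {
  fs <- fitted_small()
  alien <- fs$s[1:3, ]
  alien$specialty <- "astrology"
  alien$appointment_id <- paste0("Z", 1:3)
  rl <- rank_appointments(fs$f, rbind(fs$s, alien))
  expect_equal(nrow(attr(rl, "skipped")), 3)
  expect_false(any(rl$specialty == "astrology"))
})

test_that("a threshold exceeded by 27% of 1,000 appointments flags 270", {
  set.seed(21)
  probs <- seq(0.999, 0.001, length.out = 1000)
  s <- data.frame(
    appointment_id = sprintf("A%04d", 1:1000),
    patient_id = "P1", specialty = "cardiology",
    scheduled_datetime = as.POSIXct("2021-03-01 10:00:00", tz = "UTC"),
    created_date = as.Date("2021-02-01"), age_group = "teenager",
    sex = "female", commune = "macul", insurance = "B",
    appointment_type = "routine", outcome = NA_integer_,
    stringsAsFactors = FALSE)
  # bypass fitting: a stub model whose scorer returns fixed probabilities
  rl <- structure(data.frame(
    rank = 1:1000, appointment_id = s$appointment_id,
    patient_id = s$patient_id, specialty = s$specialty,
    scheduled_datetime = s$scheduled_datetime, probability = probs,
    flagged = as.integer(probs >= probs[270])),
    class = c("ranked_list", "data.frame"))
  expect_equal(sum(rl$flagged), 270)
  cc <- confusion_counts(rbinom(1000, 1, 0.2), rl$flagged)
  expect_equal(proportion_actions(cc), 0.27)
})

test_that("top_k takes exact counts and half-up fractions", {
  fs <- fitted_small()
  rl <- rank_appointments(fs$f, fs$s)
  expect_equal(nrow(top_k(rl, k = 1)), 1)
  expect_equal(nrow(top_k(rl, k = nrow(rl))), nrow(rl))
  expect_error(top_k(rl, k = nrow(rl) + 1), "between")

  frac <- top_k(rl, fraction = 0.05)
  expect_equal(nrow(frac), floor(0.05 * nrow(rl) + 0.5))
  # the published arithmetic: 5% of 4,617 appointments -> 231 calls
  expect_equal(floor(0.05 * 4617 + 0.5), 231)
})

test_that("ranked confusion counts agree with the metric layer", {
  fs <- fitted_small()
  rl <- rank_appointments(fs$f, fs$s)
  cc <- ranked_confusion(rl, fs$s)
  probs <- predict(fs$f, fs$s)
  thr <- vapply(fs$f$models, `[[`, numeric(1), "threshold")
  direct <- confusion_counts(
    fs$s$outcome, as.integer(probs >= thr[fs$s$specialty]))
  expect_identical(cc, direct)
})
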