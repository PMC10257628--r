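# Feature engineering: history, delay, encoding, look-back correlation.

test_that("historical no-show rates are hand-countable and causal", {
  s <- tiny_schedule()
  h <- compute_historical_noshow(s)
  # patient P1, 4th appointment: prior outcomes (0, 1, 1) -> 2/3
  expect_equal(h$hist_noshow[4], 2 / 3)
  # by specialty (cardiology): priors (0, 1) -> 1/2
  expect_equal(h$hist_noshow_spec[4], 1 / 2)
  # first-ever appointments: rate 0 with the indicator set
  expect_equal(h$hist_noshow[c(1, 5)], c(0, 0))
  expect_equal(h$first_visit[c(1, 5)], c(1L, 1L))
  # 3rd appointment is P1's first dermatology visit
  expect_equal(h$first_visit_spec[3], 1L)
  expect_equal(h$hist_noshow[3], 1 / 2)

  # changing records dated after appointment i leaves i's features intact
  s2 <- s
  s2$outcome[4] <- 1L
  h2 <- compute_historical_noshow(s2)
  expect_equal(h2[1:3, ], h[1:3, ])

  expect_error(compute_historical_noshow(
    transform(s, appointment_id = "X")), "duplicated")
})

test_that("prior appointments with unknown outcomes are excluded", {
  s <- tiny_schedule()
  s$outcome[2] <- NA
  h <- compute_historical_noshow(s)
  # priors for appointment 4: known outcomes (0, 1) -> 1/2
  expect_equal(h$hist_noshow[4], 1 / 2)
  expect_equal(h$n_prior[4], 2L)
})

test_that("reservation delay is the floor of the day difference over 7", {
  d0 <- as.Date("2020-03-02")
  expect_equal(reservation_delay_weeks(d0, d0), 0L)
  expect_equal(reservation_delay_weeks(d0, d0 + 13), 1L)
  expect_equal(reservation_delay_weeks(d0, d0 + 42), 6L)
  expect_error(reservation_delay_weeks(d0, d0 - 1), "after")
})

test_that("one-hot encoding partitions each categorical feature", {
  s <- default_schedule()[1:400, ]
  enc <- encode_features(s)
  for (feat in c("age_group", "sex", "commune", "insurance",
                 "appointment_type", "day_of_week", "month", "hour")) {
    cols <- grep(paste0("^", feat, "="), colnames(enc$x))
    expect_gt(length(cols), 0)
    expect_equal(unname(rowSums(enc$x[, cols, drop = FALSE])),
                 rep(1, nrow(s)))
  }
  expect_true(all(enc$x >= 0 & enc$x <= 1))
})

test_that("two records differing only in sex differ in the sex columns", {
  s <- tiny_schedule()[c(1, 5), ]
  s$patient_id <- c("P1", "P2")
  s[2, c("specialty", "scheduled_datetime", "created_date", "age_group",
         "commune", "insurance", "appointment_type", "outcome")] <-
    s[1, c("specialty", "scheduled_datetime", "created_date", "age_group",
           "commune", "insurance", "appointment_type", "outcome")]
  enc <- encode_features(s)
  diffs <- which(enc$x[1, ] != enc$x[2, ])
  expect_equal(sort(names(diffs)), c("sex=female", "sex=male"))
})

test_that("min-max scaling and schema reuse behave as a frozen contract", {
  s <- tiny_schedule()
  s$created_date <- as.Date(s$scheduled_datetime, tz = "UTC") -
    c(0, 35, 70, 0, 35)  # delays 0, 5, 10 weeks
  enc <- encode_features(s)
  expect_equal(unname(enc$x[1:3, "reservation_delay"]), c(0, 0.5, 1))

  # idempotence: applying the learned schema reproduces the matrix
  enc2 <- encode_features(s, schema = enc$schema)
  expect_identical(enc$x, enc2$x)

  # unseen category encodes to an all-zero block, not an error
  s2 <- s
  s2$commune[1] <- "somewhere_else"
  enc3 <- encode_features(s2, schema = enc$schema)
  cols <- grep("^commune=", colnames(enc3$x))
  expect_equal(sum(enc3$x[1, cols]), 0)
  # delays beyond the training range clip to 1
  s3 <- s
  s3$created_date[2] <- as.Date(s3$scheduled_datetime[2], tz = "UTC") - 200
  enc4 <- encode_features(s3, schema = enc$schema)
  expect_equal(unname(enc4$x[2, "reservation_delay"]), 1)
})

test_that("binned delay encoding produces per-week indicator columns", {
  s <- default_schedule()[1:500, ]
  enc <- encode_features(s, delay = "binned")
  expect_true("delay_weeks=w0" %in% colnames(enc$x))
  expect_false("reservation_delay" %in% colnames(enc$x))
  cols <- grep("^delay_weeks=", colnames(enc$x))
  expect_equal(unname(rowSums(enc$x[, cols])), rep(1, nrow(s)))
})

test_that("look-back correlation grows with the window size", {
  s <- default_schedule()
  r6 <- lookback_correlation(s, 6)
  r_full <- lookback_correlation(s, Inf)
  expect_gt(r_full$r, 0)
  expect_gt(r_full$r, r6$r)

  # a window long enough to hold every history equals full history
  r_wide <- lookback_correlation(s, 1e6)
  expect_equal(r_wide$r, r_full$r)

  expect_error(lookback_correlation(s, 0), "positive")
  expect_error(lookback_correlation(s[1:2, ], Inf), "fewer than 3")
})

test_that("independent outcomes give a look-back correlation near zero", {
  cfg <- sim_config(n_patients = 1500, latent_propensity_sd = 0,
                    effects = lapply(default_effects(), function(x) x * 0),
                    seed = 31)
  s <- generate_schedule(cfg)
  res <- lookback_correlation(s, Inf)
  expect_lt(abs(res$r), 3 / sqrt(res$n))
})
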