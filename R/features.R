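# Feature engineering: leakage-safe historical no-show rates, reservation
# delay, and one-hot/min-max encoding with a frozen schema.

#' Reservation delay in whole weeks
#'
#' Time from the creation of a reservation to the appointment itself,
#' `floor(days / 7)`. A delay of 0 weeks (booked within the same week)
#' is the strongest attendance predictor in this problem.
#'
#' @param created_date Date (or coercible) when the reservation was made.
#' @param scheduled_datetime POSIXct/Date of the appointment.
#' @return Non-negative integer vector of weeks.
#' @examples
#' reservation_delay_weeks(as.Date("2020-01-01"), as.Date("2020-01-14"))
#' @export
reservation_delay_weeks <- function(created_date, scheduled_datetime) {
  days <- as.integer(as.Date(scheduled_datetime, tz = "UTC") -
                       as.Date(created_date))
  if (anyNA(days)) stop("unparseable dates", call. = FALSE)
  if (any(days < 0L)) {
    stop("created_date after scheduled date at position(s): ",
         paste(utils::head(which(days < 0L), 5), collapse = ", "),
         call. = FALSE)
  }
  days %/% 7L
}

# order records causally: per patient by time, ties broken by appointment_id
causal_order <- function(records) {
  order(records$patient_id, records$scheduled_datetime,
        records$appointment_id)
}

lagged_cumsum_by <- function(x, group) {
  cs <- stats::ave(x, group, FUN = cumsum)
  cs - x
}

#' Leakage-safe historical no-show features
#'
#' For every appointment, the fraction of the patient's strictly prior
#' appointments that were no-shows — overall and restricted to the current
#' specialty. "Prior" is defined by scheduled time with ties broken by
#' `appointment_id`, so the computation is deterministic and causal: rows
#' dated after an appointment can never influence its features. Prior
#' appointments with unknown outcome (`NA`) are excluded from both numerator
#' and denominator.
#'
#' A patient's first appointment has no history; its rates are set to 0 and
#' the companion `first_visit` / `first_visit_spec` indicators are set to 1
#' so that new patients are not conflated with perfect attenders.
#'
#' @param records schedule data.frame (outcome may contain `NA`).
#' @return data.frame aligned to `records` rows: `appointment_id`,
#'   `hist_noshow`, `hist_noshow_spec`, `n_prior`, `n_prior_spec`,
#'   `first_visit`, `first_visit_spec`.
#' @export
compute_historical_noshow <- function(records) {
  if (anyDuplicated(records$appointment_id)) {
    stop("duplicated appointment_id", call. = FALSE)
  }
  n <- nrow(records)
  ord <- causal_order(records)
  known <- as.numeric(!is.na(records$outcome))[ord]
  miss <- ifelse(is.na(records$outcome), 0, records$outcome)[ord]
  pid <- records$patient_id[ord]
  pspec <- paste(pid, records$specialty[ord], sep = "\r")

  n_prior <- lagged_cumsum_by(known, pid)
  ns_prior <- lagged_cumsum_by(miss * known, pid)
  n_prior_s <- lagged_cumsum_by(known, pspec)
  ns_prior_s <- lagged_cumsum_by(miss * known, pspec)

  out <- data.frame(
    appointment_id = records$appointment_id[ord],
    hist_noshow = ifelse(n_prior > 0, ns_prior / pmax(n_prior, 1), 0),
    hist_noshow_spec = ifelse(n_prior_s > 0,
                              ns_prior_s / pmax(n_prior_s, 1), 0),
    n_prior = as.integer(n_prior),
    n_prior_spec = as.integer(n_prior_s),
    first_visit = as.integer(n_prior == 0),
    first_visit_spec = as.integer(n_prior_s == 0),
    stringsAsFactors = FALSE
  )
  out[match(records$appointment_id, out$appointment_id), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  stopifnot(nrow(out) == n)
  out
}

categorical_features <- function(include_specialty = FALSE,
                                 delay_binned = FALSE) {
  base <- c("age_group", "sex", "commune", "insurance", "appointment_type",
            "day_of_week", "month", "hour")
  if (delay_binned) base <- c(base, "delay_weeks")
  if (include_specialty) base <- c("specialty", base)
  base
}

# raw (pre-encoding) feature columns derived from a schedule
derive_raw_features <- function(records) {
  lt <- as.POSIXlt(records$scheduled_datetime, tz = "UTC")
  hist <- compute_historical_noshow(records)
  delay <- reservation_delay_weeks(records$created_date,
                                   records$scheduled_datetime)
  data.frame(
    specialty = records$specialty,
    age_group = records$age_group, sex = records$sex,
    commune = records$commune, insurance = records$insurance,
    appointment_type = records$appointment_type,
    day_of_week = weekday_name(as.Date(records$scheduled_datetime,
                                       tz = "UTC")),
    month = month.abb[lt$mon + 1L],
    hour = sprintf("h%02d", lt$hour),
    delay_weeks = ifelse(delay >= 10L, "w10plus", sprintf("w%d", delay)),
    reservation_delay = delay,
    hist_noshow = hist$hist_noshow,
    hist_noshow_spec = hist$hist_noshow_spec,
    first_visit = hist$first_visit,
    first_visit_spec = hist$first_visit_spec,
    stringsAsFactors = FALSE
  )
}

#' Encode appointment records into a model feature matrix
#'
#' Implements the model's input representation: every categorical feature
#' (age group, sex, commune, insurance, appointment type, day of week,
#' month, hour of day — plus specialty for pooled models) is one-hot
#' encoded; the numeric features (historical no-show overall and by
#' specialty, reservation delay) are scaled to `[0, 1]`, with min-max
#' parameters learned from the data and frozen in the returned schema.
#' First-visit indicator columns mark appointments with no usable history.
#'
#' When `schema` is `NULL` the vocabulary and scaling are learned from
#' `records` (training path); otherwise the given schema is applied
#' unchanged (test/deployment path): categories unseen at training time
#' yield all-zero indicators for that feature, and scaled numerics are
#' clipped into `[0, 1]`.
#'
#' @param records schedule data.frame.
#' @param schema a `feature_schema` from a previous call, or `NULL` to learn
#'   one.
#' @param delay `"numeric"` (default) scales the week count to `[0, 1]`;
#'   `"binned"` one-hot encodes weeks 0-9 and a 10+ bucket instead (the
#'   representation used for per-week correlation/importance reports).
#' @param include_specialty add one specialty indicator per row (pooled
#'   model path).
#' @return list with `x` (numeric matrix, rows named by appointment id),
#'   `y` (integer outcome vector, or `NULL` if outcomes are absent), and
#'   `schema` (class `feature_schema`).
#' @export
encode_features <- function(records, schema = NULL,
                            delay = c("numeric", "binned"),
                            include_specialty = FALSE) {
  if (nrow(records) == 0L) stop("no records to encode", call. = FALSE)
  raw <- derive_raw_features(records)
  if (is.null(schema)) {
    delay <- match.arg(delay)
    schema <- learn_schema(raw, delay, include_specialty)
  } else {
    if (!inherits(schema, "feature_schema")) {
      stop("schema must be a feature_schema", call. = FALSE)
    }
    if (!identical(schema$version, 1L)) {
      stop("feature schema version mismatch", call. = FALSE)
    }
  }
  x <- apply_schema(raw, schema)
  rownames(x) <- records$appointment_id
  y <- if ("outcome" %in% names(records) && !anyNA(records$outcome)) {
    as.integer(records$outcome)
  } else {
    NULL
  }
  list(x = x, y = y, schema = schema)
}

# learn vocabulary and scaling from (training) raw features
learn_schema <- function(raw, delay = "numeric",
                         include_specialty = FALSE) {
  cats <- categorical_features(include_specialty, delay == "binned")
  vocab <- lapply(raw[cats], function(x) sort(unique(x)))
  numeric_range <- if (delay == "numeric") {
    list(reservation_delay = range(raw$reservation_delay))
  } else {
    list()
  }
  structure(
    list(delay = delay, include_specialty = include_specialty,
         vocabulary = vocab, numeric_range = numeric_range, version = 1L),
    class = "feature_schema")
}

# apply a frozen schema to raw features; unseen categories encode to zero
apply_schema <- function(raw, schema) {
  blocks <- lapply(names(schema$vocabulary), function(feat) {
    levs <- schema$vocabulary[[feat]]
    m <- vapply(levs, function(l) as.numeric(raw[[feat]] == l),
                numeric(nrow(raw)))
    if (nrow(raw) == 1L) m <- matrix(m, nrow = 1L)
    colnames(m) <- paste(feat, levs, sep = "=")
    m
  })
  x <- do.call(cbind, blocks)
  num <- cbind(hist_noshow = raw$hist_noshow,
               hist_noshow_spec = raw$hist_noshow_spec,
               first_visit = as.numeric(raw$first_visit),
               first_visit_spec = as.numeric(raw$first_visit_spec))
  if (schema$delay == "numeric") {
    rng <- schema$numeric_range$reservation_delay
    span <- rng[2] - rng[1]
    scaled <- if (span == 0) rep(0, nrow(raw)) else
      (raw$reservation_delay - rng[1]) / span
    num <- cbind(num, reservation_delay = pmin(pmax(scaled, 0), 1))
  }
  cbind(x, num)
}

#' @export
print.feature_schema <- function(x, ...) {
  nlev <- vapply(x$vocabulary, length, integer(1))
  cat("Feature schema (version", x$version, ")\n")
  cat(" delay representation:", x$delay, "\n")
  cat(" categorical features:",
      paste(sprintf("%s(%d)", names(nlev), nlev), collapse = ", "), "\n")
  cat(" numeric features: hist_noshow, hist_noshow_spec",
      if (x$delay == "numeric") ", reservation_delay (min-max scaled)",
      "\n", sep = "")
  invisible(x)
}

#' Correlation between no-show and windowed attendance history
#'
#' For each appointment with at least one prior appointment (with a known
#' outcome) inside the look-back window, computes the windowed prior
#' no-show fraction and returns its Pearson correlation with the outcome.
#' Used to choose the look-back period: with a stable per-patient
#' propensity, longer windows average away noise and the correlation grows
#' with window size.
#'
#' @param records labeled schedule data.frame.
#' @param window_months look-back window in months (`Inf` = full history).
#' @return list with `r` (Pearson correlation), `n` (number of eligible
#'   appointments), and `window_months`.
#' @export
lookback_correlation <- function(records, window_months = Inf) {
  if (!is.infinite(window_months) && window_months <= 0) {
    stop("window_months must be positive or Inf", call. = FALSE)
  }
  ord <- causal_order(records)
  r <- records[ord, , drop = FALSE]
  window_days <- window_months * 30.4375
  t_num <- as.numeric(r$scheduled_datetime)
  win <- window_days * 86400

  rates <- rep(NA_real_, nrow(r))
  start <- 1L
  for (i in seq_len(nrow(r))) {
    if (i > 1L && r$patient_id[i] != r$patient_id[i - 1L]) start <- i
    if (i == start) next
    j <- start:(i - 1L)
    ok <- !is.na(r$outcome[j]) &
      (is.infinite(win) | t_num[j] >= t_num[i] - win)
    if (any(ok)) rates[i] <- mean(r$outcome[j][ok])
  }
  eligible <- !is.na(rates) & !is.na(r$outcome)
  if (sum(eligible) < 3L) {
    stop("fewer than 3 appointments with windowed history", call. = FALSE)
  }
  list(r = stats::cor(r$outcome[eligible], rates[eligible]),
       n = sum(eligible), window_months = window_months)
}
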