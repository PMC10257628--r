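# Synthetic longitudinal appointment schedules.
#
# The generator emulates the statistical structure the downstream pipeline
# assumes: a pediatric outpatient schedule with a roughly 31:8 show:no-show
# imbalance, per-specialty heterogeneity in no-show rates, a per-patient
# latent propensity (so that the historical no-show feature is genuinely
# predictive), and a point mass of same-week reservations that strongly
# predicts attendance.

specialty_vocab <- function() {
  # specialty names with marginal no-show rates (proportions)
  c(pulmonology = 0.232, ophthalmology = 0.303, cardiology = 0.147,
    oncology = 0.049, general_surgery = 0.169, otorhinolaryngology = 0.227,
    plastic_surgery = 0.142, psychiatry = 0.240, dermatology = 0.281,
    rheumatology = 0.209, endocrinology = 0.221, traumatology = 0.199,
    gastroenterology = 0.193, urology = 0.193, gynecology = 0.251,
    genetics = 0.245, hematology = 0.158, pediatrics = 0.226,
    nephrology = 0.184, infectology = 0.237, neurology = 0.283,
    parasitology = 0.188, nutrition = 0.276, pediatric_dentistry = 0.249,
    orthodontics = 0.184)
}

category_levels <- function() {
  list(
    age_group = c("nursling", "first_infancy", "second_infancy",
                  "teenager", "young_adult"),
    sex = c("female", "male"),
    commune = c("penalolen", "macul", "nunoa", "lo_barnechea", "las_condes",
                "providencia", "la_reina", "vitacura", "easter_island",
                "other_santiago", "rest_of_country"),
    insurance = c("A", "B", "C", "D", "provisory", "private"),
    appointment_type = c("first_time", "routine", "first_time_phc", "other"),
    hour = as.character(8:17),
    day_of_week = c("Mon", "Tue", "Wed", "Thu", "Fri"),
    month = month.abb
  )
}

category_probs <- function() {
  list(
    age_group = c(0.097, 0.241, 0.392, 0.262, 0.008),
    sex = c(0.5, 0.5),
    commune = c(0.311, 0.124, 0.089, 0.048, 0.046, 0.041, 0.041, 0.005,
                0.002, 0.111, 0.182),
    insurance = c(0.441, 0.221, 0.130, 0.173, 0.020, 0.015),
    appointment_type = c(0.231, 0.637, 0.087, 0.045)
  )
}

#' Default log-odds effect coefficients for the generator
#'
#' Named list mapping each raw feature to per-category log-odds
#' contributions. Defaults are chosen so that the simulated data reproduce
#' the qualitative correlation structure seen in pediatric no-show data:
#' same-week reservations strongly predict attendance, first-time and
#' primary-care-derived appointments and early-morning slots are missed more
#' often, the lowest-income insurance tier and the poorest communes miss
#' more, patients travelling from outside the capital miss less, and
#' teenagers miss more than nurslings. Categories not listed contribute 0.
#' Within each feature the nonzero values are roughly centred under the
#' category frequencies, so the marginal prevalence is governed by the
#' intercept alone.
#'
#' @return Named list of named numeric vectors (`delay0` is a single value:
#'   the log-odds contribution of a reservation delay of 0 weeks).
#' @export
default_effects <- function() {
  list(
    delay0 = c(delay0 = -0.9),
    appointment_type = c(first_time = 0.30, routine = -0.20,
                         first_time_phc = 0.35),
    hour = c(`8` = 0.30, `11` = -0.30),
    insurance = c(A = 0.20, D = -0.35),
    commune = c(penalolen = 0.25, macul = 0.20, rest_of_country = -0.45),
    age_group = c(teenager = 0.20, nursling = -0.30),
    sex = c(),
    day_of_week = c(Mon = 0.20, Wed = -0.20),
    month = c(Dec = 0.20, May = -0.20)
  )
}

#' Configuration for the synthetic schedule generator
#'
#' @param n_patients number of patients.
#' @param n_specialties number of specialties drawn from the built-in
#'   vocabulary (ignored when `specialties` is given).
#' @param specialties optional character vector of specialty names.
#' @param specialty_rates optional named vector of per-specialty target
#'   no-show rates; when given, each specialty is calibrated to its own rate
#'   instead of the global `target_prevalence`.
#' @param window_start,window_end study window (Dates); appointments fall on
#'   weekdays within it.
#' @param visits_size,visits_mu zero-truncated negative-binomial parameters
#'   for the number of appointments per patient.
#' @param target_prevalence marginal no-show proportion the intercept is
#'   calibrated to; default 8/39, an approximately 31:8 show:no-show ratio.
#' @param base_logit baseline log-odds used verbatim when
#'   `calibrate = FALSE`; default `qlogis(target_prevalence)`.
#' @param calibrate logical; when `TRUE` (default) the intercept is solved
#'   numerically so the expected prevalence matches the target exactly given
#'   the simulated covariates and random effects.
#' @param latent_propensity_sd standard deviation of the per-patient
#'   Gaussian random effect on the logit.
#' @param delay_zero_prob point mass of a 0-week reservation delay.
#' @param delay_size,delay_mu,delay_max negative-binomial parameters (and
#'   cap) for the positive part of the delay, in weeks.
#' @param effects log-odds effect map, see [default_effects()].
#' @param visit_home_prob probability that an appointment belongs to the
#'   patient's primary specialty (the rest are spread uniformly), so that
#'   within-specialty histories exist.
#' @param seed integer seed; all randomness in [generate_schedule()] flows
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 4000,
                       n_specialties = 8,
                       specialties = NULL,
                       specialty_rates = NULL,
                       window_start = as.Date("2016-01-01"),
                       window_end = as.Date("2017-12-31"),
                       visits_size = 1.2,
                       visits_mu = 6,
                       target_prevalence = 8 / 39,
                       base_logit = NULL,
                       calibrate = TRUE,
                       latent_propensity_sd = 0.9,
                       delay_zero_prob = 0.30,
                       delay_size = 2,
                       delay_mu = 4,
                       delay_max = 40,
                       effects = default_effects(),
                       visit_home_prob = 0.7,
                       seed = 1L) {
  vocab <- specialty_vocab()
  if (is.null(specialties)) {
    if (n_specialties < 1L || n_specialties > length(vocab)) {
      stop("n_specialties must be between 1 and ", length(vocab),
           call. = FALSE)
    }
    specialties <- names(vocab)[seq_len(n_specialties)]
  }
  if (!is.null(specialty_rates)) {
    if (is.null(names(specialty_rates)) ||
        !all(specialties %in% names(specialty_rates))) {
      stop("specialty_rates must be named and cover every specialty",
           call. = FALSE)
    }
    specialty_rates <- specialty_rates[specialties]
    if (any(specialty_rates <= 0 | specialty_rates >= 1)) {
      stop("specialty_rates must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  if (n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (window_end < window_start) stop("empty study window", call. = FALSE)
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    stop("target_prevalence must lie in (0, 1)", call. = FALSE)
  }
  if (latent_propensity_sd < 0) {
    stop("latent_propensity_sd must be >= 0", call. = FALSE)
  }
  if (!all(vapply(effects, function(v) all(is.finite(v)) || length(v) == 0L,
                  logical(1)))) {
    stop("effect coefficients must be finite", call. = FALSE)
  }
  if (is.null(base_logit)) base_logit <- stats::qlogis(target_prevalence)
  cfg <- list(
    n_patients = as.integer(n_patients), specialties = specialties,
    specialty_rates = specialty_rates, window_start = window_start,
    window_end = window_end, visits_size = visits_size,
    visits_mu = visits_mu, target_prevalence = target_prevalence,
    base_logit = base_logit, calibrate = isTRUE(calibrate),
    latent_propensity_sd = latent_propensity_sd,
    delay_zero_prob = delay_zero_prob, delay_size = delay_size,
    delay_mu = delay_mu, delay_max = delay_max, effects = effects,
    visit_home_prob = visit_home_prob, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# locale-independent weekday (Mon = 1 .. Sun = 7) and month names
weekday_index <- function(d) ((as.integer(d) + 3L) %% 7L) + 1L
weekday_name <- function(d) {
  c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")[weekday_index(d)]
}
month_name <- function(d) month.abb[as.POSIXlt(d)$mon + 1L]

# zero-truncated negative binomial via the inverse-cdf trick
rztnb <- function(n, size, mu) {
  p0 <- stats::pnbinom(0, size = size, mu = mu)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnbinom(u, size = size, mu = mu)
}

effect_lookup <- function(effects, feature, values) {
  coefs <- effects[[feature]]
  if (is.null(coefs) || length(coefs) == 0L) return(numeric(length(values)))
  out <- coefs[values]
  out[is.na(out)] <- 0
  unname(out)
}

#' Generate a synthetic appointment schedule
#'
#' Draws a longitudinal schedule under a logistic outcome model: the no-show
#' log-odds of an appointment are an intercept (calibrated to the target
#' prevalence) plus the configured covariate effects plus a per-patient
#' Gaussian random effect. The random effect makes a patient's past no-show
#' fraction genuinely predictive of future no-shows, which is what the
#' historical-no-show feature exploits downstream.
#'
#' @param config a [sim_config()] object.
#' @return A data.frame with one row per appointment and columns
#'   `appointment_id`, `patient_id`, `specialty`, `scheduled_datetime`
#'   (POSIXct, UTC), `created_date` (Date), `age_group`, `sex`, `commune`,
#'   `insurance`, `appointment_type`, `outcome` (integer 0/1, 1 = no-show).
#'   Deterministic given `config` (including its seed).
#' @examples
#' sched <- generate_schedule(sim_config(n_patients = 50, seed = 7))
#' mean(sched$outcome)
#' @export
generate_schedule <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be created with sim_config()", call. = FALSE)
  }
  set.seed(config$seed)
  lv <- category_levels()
  pr <- category_probs()
  np <- config$n_patients

  visits <- rztnb(np, config$visits_size, config$visits_mu)
  n <- sum(visits)
  latent <- stats::rnorm(np, 0, config$latent_propensity_sd)

  patient <- list(
    age_group = sample(lv$age_group, np, TRUE, pr$age_group),
    sex = sample(lv$sex, np, TRUE, pr$sex),
    commune = sample(lv$commune, np, TRUE, pr$commune / sum(pr$commune)),
    insurance = sample(lv$insurance, np, TRUE, pr$insurance),
    home = sample(config$specialties, np, TRUE)
  )

  idx <- rep.int(seq_len(np), visits)

  # specialty: mostly the patient's home specialty, remainder uniform
  is_home <- stats::runif(n) < config$visit_home_prob
  other <- sample(config$specialties, n, TRUE)
  specialty <- ifelse(is_home, patient$home[idx], other)

  weekday_pool <- seq(config$window_start, config$window_end, by = "day")
  weekday_pool <- weekday_pool[weekday_index(weekday_pool) <= 5L]
  if (length(weekday_pool) == 0L) {
    stop("study window contains no weekdays", call. = FALSE)
  }
  sched_date <- sample(weekday_pool, n, TRUE)
  # order within patient so histories accumulate over time
  ord <- order(idx, sched_date)
  sched_date <- sched_date[ord]
  specialty <- specialty[ord]
  hour <- sample(8:17, n, TRUE)

  delay_weeks <- ifelse(
    stats::runif(n) < config$delay_zero_prob, 0L,
    pmin(1L + stats::rnbinom(n, size = config$delay_size,
                             mu = config$delay_mu), config$delay_max)
  )
  created_date <- sched_date - (7L * delay_weeks + sample(0:6, n, TRUE))

  eff <- config$effects
  eta_cov <-
    ifelse(delay_weeks == 0L, unname(eff$delay0["delay0"]), 0) +
    effect_lookup(eff, "appointment_type",
                  at <- sample(lv$appointment_type, n, TRUE,
                               pr$appointment_type)) +
    effect_lookup(eff, "hour", as.character(hour)) +
    effect_lookup(eff, "insurance", patient$insurance[idx]) +
    effect_lookup(eff, "commune", patient$commune[idx]) +
    effect_lookup(eff, "age_group", patient$age_group[idx]) +
    effect_lookup(eff, "sex", patient$sex[idx]) +
    effect_lookup(eff, "day_of_week", weekday_name(sched_date)) +
    effect_lookup(eff, "month", month_name(sched_date)) +
    latent[idx]

  eta <- eta_cov + calibrated_intercepts(config, specialty, eta_cov)
  outcome <- as.integer(stats::runif(n) < stats::plogis(eta))

  data.frame(
    appointment_id = sprintf("A%07d", seq_len(n)),
    patient_id = sprintf("P%05d", idx),
    specialty = specialty,
    scheduled_datetime = as.POSIXct(
      paste0(format(sched_date, "%Y-%m-%d"), sprintf(" %02d:00:00", hour)),
      tz = "UTC"),
    created_date = created_date,
    age_group = patient$age_group[idx],
    sex = patient$sex[idx],
    commune = patient$commune[idx],
    insurance = patient$insurance[idx],
    appointment_type = at,
    outcome = outcome,
    stringsAsFactors = FALSE
  )
}

# Solve for the intercept(s) that make the expected prevalence hit the
# target given the realized covariate/random-effect contributions.
calibrated_intercepts <- function(config, specialty, eta_cov) {
  solve_intercept <- function(etas, target) {
    stats::uniroot(function(c0) mean(stats::plogis(etas + c0)) - target,
                   lower = -20, upper = 20, tol = 1e-10)$root
  }
  if (!config$calibrate) {
    return(rep(config$base_logit, length(eta_cov)))
  }
  if (!is.null(config$specialty_rates)) {
    ints <- vapply(config$specialties, function(s) {
      solve_intercept(eta_cov[specialty == s], config$specialty_rates[[s]])
    }, numeric(1))
    return(unname(ints[match(specialty, config$specialties)]))
  }
  rep(solve_intercept(eta_cov, config$target_prevalence), length(eta_cov))
}
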