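# Shared fixtures, built in code.

# hand-built four-visit patient plus a one-visit patient; outcomes chosen
# so the historical rates are easy to count by hand
tiny_schedule <- function() {
  data.frame(
    appointment_id = sprintf("A%02d", 1:5),
    patient_id = c(rep("P1", 4), "P2"),
    specialty = c("cardiology", "cardiology", "dermatology", "cardiology",
                  "cardiology"),
    scheduled_datetime = as.POSIXct(
      c("2020-01-06 09:00:00", "2020-02-03 10:00:00",
        "2020-03-02 11:00:00", "2020-04-06 12:00:00",
        "2020-01-06 09:00:00"), tz = "UTC"),
    created_date = as.Date(c("2020-01-06", "2020-01-20", "2020-02-24",
                             "2020-03-02", "2019-12-30")),
    age_group = "second_infancy", sex = c("female", "female", "female",
                                          "female", "male"),
    commune = "penalolen", insurance = "A",
    appointment_type = c("first_time", "routine", "first_time", "routine",
                         "first_time"),
    outcome = c(0L, 1L, 1L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

# memoised synthetic schedules so expensive generations are shared
.schedule_cache <- new.env(parent = emptyenv())
cached_schedule <- function(key, config) {
  if (!exists(key, envir = .schedule_cache)) {
    assign(key, generate_schedule(config), envir = .schedule_cache)
  }
  get(key, envir = .schedule_cache)
}

# mid-size default-config schedule reused across files (~13k appointments)
default_schedule <- function() {
  cached_schedule("default2k", sim_config(n_patients = 2000, seed = 42))
}

# two sub-populations with opposite, effect-dominated covariate regimes,
# distinct specialties and patients: per-specialty heterogeneity in the
# effects themselves, not just in the intercepts — the condition under
# which indicator-augmented pooled models underperform per-specialty ones
heterogeneous_schedule <- function(n_patients = 1200, seed = 7,
                                   scale = 2.5, latent_sd = 0.45) {
  eff_a <- lapply(default_effects(), function(v) v * scale)
  eff_b <- lapply(eff_a, function(v) -v)
  a <- generate_schedule(sim_config(
    n_patients = n_patients, specialties = c("cardiology", "dermatology"),
    effects = eff_a, latent_propensity_sd = latent_sd,
    target_prevalence = 0.15, seed = seed))
  b <- generate_schedule(sim_config(
    n_patients = n_patients, specialties = c("neurology", "ophthalmology"),
    effects = eff_b, latent_propensity_sd = latent_sd,
    target_prevalence = 0.28, seed = seed + 1))
  b$patient_id <- sub("^P", "Q", b$patient_id)
  b$appointment_id <- sub("^A", "B", b$appointment_id)
  rbind(a, b)
}
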