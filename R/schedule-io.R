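# CSV persistence for appointment schedules.
#
# Column contract: appointment_id, patient_id, specialty,
# scheduled_datetime (ISO-8601), created_date (ISO-8601 date), age_group,
# sex, commune, insurance, appointment_type, outcome (0/1; optional when the
# file is read in scoring mode).

schedule_columns <- function() {
  c("appointment_id", "patient_id", "specialty", "scheduled_datetime",
    "created_date", "age_group", "sex", "commune", "insurance",
    "appointment_type", "outcome")
}

#' Write an appointment schedule to CSV
#'
#' Datetimes are written as ISO-8601 (`YYYY-MM-DDTHH:MM:SS`, UTC) and dates
#' as `YYYY-MM-DD`, so [read_schedule()] round-trips every field and the row
#' order exactly.
#'
#' @param records schedule data.frame as returned by [generate_schedule()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(records, path) {
  validate_schedule(records, require_outcome = FALSE)
  out <- records
  out$scheduled_datetime <- format(records$scheduled_datetime,
                                   "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$created_date <- format(records$created_date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an appointment schedule from CSV
#'
#' @param path CSV file path.
#' @param scoring logical; in scoring mode the `outcome` column may be
#'   absent (or empty) and is filled with `NA` — the dialect used when
#'   scoring a day of not-yet-realized appointments.
#' @return A schedule data.frame (see [generate_schedule()] for columns).
#' @export
read_schedule <- function(path, scoring = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  required <- setdiff(schedule_columns(), if (scoring) "outcome")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("schedule file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dt <- as.POSIXct(raw$scheduled_datetime, format = "%Y-%m-%dT%H:%M:%S",
                   tz = "UTC")
  if (anyNA(dt)) {
    stop("unparseable scheduled_datetime at row(s): ",
         paste(utils::head(which(is.na(dt)), 5), collapse = ", "),
         call. = FALSE)
  }
  cd <- as.Date(raw$created_date, format = "%Y-%m-%d")
  if (anyNA(cd)) {
    stop("unparseable created_date at row(s): ",
         paste(utils::head(which(is.na(cd)), 5), collapse = ", "),
         call. = FALSE)
  }
  outcome <- if ("outcome" %in% names(raw)) {
    suppressWarnings(as.integer(raw$outcome))
  } else {
    rep(NA_integer_, nrow(raw))
  }
  records <- data.frame(
    appointment_id = raw$appointment_id, patient_id = raw$patient_id,
    specialty = raw$specialty, scheduled_datetime = dt, created_date = cd,
    age_group = raw$age_group, sex = raw$sex, commune = raw$commune,
    insurance = raw$insurance, appointment_type = raw$appointment_type,
    outcome = outcome, stringsAsFactors = FALSE
  )
  validate_schedule(records, require_outcome = !scoring)
  records
}

#' Validate schedule invariants
#'
#' Checks the schema contract: unique appointment ids, creation date not
#' after the scheduled date, scheduled hour within the 8-17 clinic day, and
#' (unless scoring) a binary outcome. Violations name the offending rows.
#'
#' @param records schedule data.frame.
#' @param require_outcome logical; require a complete 0/1 outcome column.
#' @return `records`, invisibly.
#' @export
validate_schedule <- function(records, require_outcome = TRUE) {
  missing <- setdiff(setdiff(schedule_columns(), "outcome"), names(records))
  if (length(missing) > 0L) {
    stop("schedule is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(records$appointment_id)
  if (any(dup)) {
    stop("duplicated appointment_id at row(s): ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }
  bad <- records$created_date > as.Date(records$scheduled_datetime,
                                        tz = "UTC")
  if (any(bad)) {
    stop("created_date after scheduled date at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  hr <- as.POSIXlt(records$scheduled_datetime, tz = "UTC")$hour
  if (any(hr < 8L | hr > 17L)) {
    stop("scheduled hour outside the 8-17 clinic day at row(s): ",
         paste(utils::head(which(hr < 8L | hr > 17L), 5), collapse = ", "),
         call. = FALSE)
  }
  if (require_outcome) {
    if (!"outcome" %in% names(records) || anyNA(records$outcome) ||
        !all(records$outcome %in% c(0L, 1L))) {
      stop("outcome column must be complete 0/1 (use scoring mode for ",
           "unlabeled schedules)", call. = FALSE)
    }
  }
  invisible(records)
}
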