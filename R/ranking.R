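# Deployment stage: score a day's schedule, emit a descending-risk call
# list, flag the appointments to contact.

#' Rank appointments by predicted no-show probability
#'
#' Scores a schedule with a fitted model (or set of models) and returns the
#' deployment call list: appointments sorted by predicted no-show
#' probability in descending order, ties broken by ascending appointment
#' id, with a flag for every appointment at or above the model's
#' classification threshold. The output is invariant to the input row
#' order.
#'
#' Appointments from specialties without a model are not scored; they are
#' returned in the `skipped` attribute rather than causing an error.
#'
#' @param object a `noshow_fit` or single `noshow_model`.
#' @param records schedule data.frame (outcome optional; appointments being
#'   scored for a future day carry `NA` outcomes, while their patients'
#'   past labeled rows supply the history).
#' @return A data.frame of class `ranked_list` with columns `rank`,
#'   `appointment_id`, `patient_id`, `specialty`, `scheduled_datetime`,
#'   `probability`, `flagged`; attribute `skipped` holds unscored rows.
#' @export
rank_appointments <- function(object, records) {
  validate_schedule(records, require_outcome = FALSE)
  if (inherits(object, "noshow_model")) {
    models <- stats::setNames(list(object), object$specialty)
    pooled <- isTRUE(object$pooled)
  } else if (inherits(object, "noshow_fit")) {
    models <- object$models
    pooled <- object$pooled
  } else {
    stop("object must be a noshow_fit or noshow_model", call. = FALSE)
  }
  groups <- if (pooled) rep("pooled", nrow(records)) else records$specialty
  scored <- groups %in% names(models)

  probs <- rep(NA_real_, nrow(records))
  thresholds <- rep(NA_real_, nrow(records))
  for (g in unique(groups[scored])) {
    sel <- which(groups == g)
    probs[sel] <- predict(models[[g]], records[sel, , drop = FALSE])
    thresholds[sel] <- models[[g]]$threshold
  }

  keep <- which(scored)
  ord <- keep[order(-probs[keep], records$appointment_id[keep])]
  out <- data.frame(
    rank = seq_along(ord),
    appointment_id = records$appointment_id[ord],
    patient_id = records$patient_id[ord],
    specialty = records$specialty[ord],
    scheduled_datetime = records$scheduled_datetime[ord],
    probability = probs[ord],
    flagged = as.integer(probs[ord] >= thresholds[ord]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ranked_list", "data.frame")
  attr(out, "skipped") <- records[!scored, , drop = FALSE]
  out
}

#' @export
print.ranked_list <- function(x, n = 10, ...) {
  cat("Ranked call list:", nrow(x), "appointments,", sum(x$flagged),
      "flagged\n")
  skipped <- attr(x, "skipped")
  if (!is.null(skipped) && nrow(skipped) > 0L) {
    cat(" (", nrow(skipped), "appointments from unmodelled specialties",
        "not scored )\n")
  }
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' Take the top of a ranked call list
#'
#' @param ranked a `ranked_list`.
#' @param k number of rows to keep.
#' @param fraction alternatively, a fraction of the list; converted to a
#'   count by rounding half-up.
#' @return The first `k` rows, still a `ranked_list`.
#' @examples
#' \donttest{top_k(ranked, fraction = 0.05)}
#' @export
top_k <- function(ranked, k = NULL, fraction = NULL) {
  if (!inherits(ranked, "ranked_list")) {
    stop("ranked must be a ranked_list", call. = FALSE)
  }
  n <- nrow(ranked)
  if (is.null(k)) {
    if (is.null(fraction)) stop("give k or fraction", call. = FALSE)
    if (fraction <= 0 || fraction > 1) {
      stop("fraction must lie in (0, 1]", call. = FALSE)
    }
    k <- floor(fraction * n + 0.5)  # round half-up
    k <- max(k, 1L)
  }
  if (k < 1L || k > n) {
    stop("k must lie between 1 and ", n, call. = FALSE)
  }
  out <- ranked[seq_len(k), , drop = FALSE]
  class(out) <- c("ranked_list", "data.frame")
  attr(out, "skipped") <- attr(ranked, "skipped")
  out
}

#' Confusion counts implied by a labeled ranked list
#'
#' Joins a ranked list back to its labeled schedule and cross-tabulates the
#' flag decision against the realized outcomes — the single source of truth
#' (probability >= threshold) shared with the metric layer.
#'
#' @param ranked a `ranked_list`.
#' @param records labeled schedule containing the ranked appointments.
#' @return A `confusion_counts` object.
#' @export
ranked_confusion <- function(ranked, records) {
  idx <- match(ranked$appointment_id, records$appointment_id)
  if (anyNA(idx)) {
    stop("ranked list contains appointments absent from records",
         call. = FALSE)
  }
  truth <- records$outcome[idx]
  if (anyNA(truth)) {
    stop("records must be labeled to evaluate a ranked list",
         call. = FALSE)
  }
  confusion_counts(truth, ranked$flagged)
}
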