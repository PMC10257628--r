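#' Confusion counts for no-show predictions
#'
#' Cross-tabulates true and predicted binary labels, with no-show (1) as the
#' positive class. All cost-effectiveness metrics in the package are derived
#' from these four counts.
#'
#' @param truth integer/logical vector of true labels (1 = no-show).
#' @param predicted integer/logical vector of predicted labels, same length.
#' @return An object of class `confusion_counts`: a list with integer fields
#'   `TP`, `FP`, `FN`, `TN` and `N = TP + FP + FN + TN`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as_binary(truth, "truth")
  predicted <- as_binary(predicted, "predicted")
  if (length(truth) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length", call. = FALSE)
  }
  cc <- list(
    TP = sum(truth == 1L & predicted == 1L),
    FP = sum(truth == 0L & predicted == 1L),
    FN = sum(truth == 1L & predicted == 0L),
    TN = sum(truth == 0L & predicted == 0L)
  )
  cc$N <- cc$TP + cc$FP + cc$FN + cc$TN
  class(cc) <- "confusion_counts"
  cc
}

as_binary <- function(x, what) {
  if (is.logical(x)) x <- as.integer(x)
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    stop(sprintf("'%s' must be a binary 0/1 vector without NA", what),
         call. = FALSE)
  }
  as.integer(x)
}

#' Build confusion counts directly from the four cells
#'
#' @param TP,FP,FN,TN non-negative integer counts (positive class = no-show).
#' @return A `confusion_counts` object.
#' @export
as_confusion_counts <- function(TP, FP, FN, TN) {
  cells <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion cells must be non-negative integers", call. = FALSE)
  }
  cc <- as.list(as.integer(cells))
  names(cc) <- names(cells)
  cc$N <- sum(cells)
  class(cc) <- "confusion_counts"
  cc
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Confusion counts (positive = no-show)\n")
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), nrow = 2,
              dimnames = list(truth = c("no-show", "show"),
                              predicted = c("no-show", "show")))
  print(m)
  invisible(x)
}

check_n <- function(cc) {
  if (!inherits(cc, "confusion_counts")) {
    stop("expected a 'confusion_counts' object", call. = FALSE)
  }
  if (cc$N < 1L) stop("confusion counts are empty (N = 0)", call. = FALSE)
  invisible(cc)
}

#' Proportion of actions P_C
#'
#' Fraction of all appointments the model flags for an intervention (a call),
#' `(FP + TP) / N`. This is the cost proxy of the metric system: every flagged
#' appointment costs one contact attempt.
#'
#' @param cc a `confusion_counts` object.
#' @return P_C in `[0, 1]`.
#' @export
proportion_actions <- function(cc) {
  check_n(cc)
  (cc$FP + cc$TP) / cc$N
}

#' No-show proportions before and after intervention
#'
#' `NSP_i = (FN + TP) / N` is the observed no-show rate; `NSP_f = FN / N` is
#' the rate that remains if every correctly flagged no-show (TP) is converted
#' to attendance. By construction `NSP_f <= NSP_i`.
#'
#' @param cc a `confusion_counts` object.
#' @return Named numeric vector `c(NSP_i = , NSP_f = )`.
#' @export
noshow_rates <- function(cc) {
  check_n(cc)
  c(NSP_i = (cc$FN + cc$TP) / cc$N, NSP_f = cc$FN / cc$N)
}

#' No-show reduction P_R
#'
#' Fraction of actual no-shows the model catches, `TP / (FN + TP)`, equal to
#' `1 - NSP_f / NSP_i`. It measures effectiveness under the assumption that
#' each flagged no-show can be converted into attendance.
#'
#' When there are no actual no-shows (`FN + TP = 0`) the quantity is
#' undefined and `NA_real_` is returned with a warning, never a silent 0.
#'
#' @param cc a `confusion_counts` object.
#' @return P_R in `[0, 1]`, or `NA_real_` when undefined.
#' @export
reduction <- function(cc) {
  check_n(cc)
  pos <- cc$FN + cc$TP
  if (pos == 0L) {
    warning("P_R undefined: no actual no-shows in the data", call. = FALSE)
    return(NA_real_)
  }
  cc$TP / pos
}

#' Cost-effectiveness metrics m1 and m2
#'
#' `m1 = P_R / P_C` is effectiveness per unit of cost, used to pick the best
#' predictive model per specialty. `m2 = P_R * (1 - P_C)` is effectiveness
#' times the fraction of appointments left un-contacted; it is bounded in
#' `[0, 1]` and is the hyperparameter-search objective.
#'
#' `metric_m1()` returns `NA_real_` (with a warning) when `P_C = 0`: a model
#' that flags nothing has no defined effectiveness-per-action ratio. A very
#' small `P_C` with nonzero `P_R` legitimately produces large m1 values.
#'
#' @param cc a `confusion_counts` object.
#' @return A single numeric value (`NA_real_` where undefined).
#' @examples
#' cc <- as_confusion_counts(TP = 18, FP = 9, FN = 2, TN = 71)
#' metric_m1(cc)
#' metric_m2(cc)
#' @export
metric_m1 <- function(cc) {
  check_n(cc)
  p_c <- proportion_actions(cc)
  p_r <- reduction(cc)
  if (is.na(p_r)) return(NA_real_)
  if (p_c == 0) {
    warning("m1 undefined: no predicted positives (P_C = 0)", call. = FALSE)
    return(NA_real_)
  }
  p_r / p_c
}

#' @rdname metric_m1
#' @export
metric_m2 <- function(cc) {
  check_n(cc)
  p_r <- reduction(cc)
  if (is.na(p_r)) return(NA_real_)
  p_r * (1 - proportion_actions(cc))
}

#' Metrics from the (P_R, P_C) pair
#'
#' Computes m1 and m2 directly from an effectiveness proportion `p_r` and a
#' cost proportion `p_c`, the form used when the proportions come from a
#' field trial rather than a confusion matrix.
#'
#' @param p_r no-show reduction in `[0, 1]`.
#' @param p_c proportion of actions in `[0, 1]`.
#' @return A single numeric value; `m1_from_rates()` is `NA_real_` at
#'   `p_c = 0`.
#' @examples
#' m1_from_rates(p_r = 0.05, p_c = 0.01)  # 5
#' @export
m1_from_rates <- function(p_r, p_c) {
  check_proportion(p_r, "p_r")
  check_proportion(p_c, "p_c")
  if (p_c == 0) {
    warning("m1 undefined: P_C = 0", call. = FALSE)
    return(NA_real_)
  }
  p_r / p_c
}

#' @rdname m1_from_rates
#' @export
m2_from_rates <- function(p_r, p_c) {
  check_proportion(p_r, "p_r")
  check_proportion(p_c, "p_c")
  p_r * (1 - p_c)
}

check_proportion <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single proportion in [0, 1]", what),
         call. = FALSE)
  }
  invisible(x)
}

#' Post-intervention no-show rate implied by a reduction
#'
#' Applies the reduction identity `NSP_f = (1 - P_R) * NSP_i`: starting from
#' a no-show rate `nsp_i`, a model with effectiveness `p_r` leaves a rate of
#' `(1 - p_r) * nsp_i` if all flagged no-shows attend.
#'
#' @param nsp_i initial no-show proportion in `[0, 1]`.
#' @param p_r no-show reduction in `[0, 1]`.
#' @return The implied final no-show proportion.
#' @examples
#' project_noshow_rate(0.20, 0.49)  # 0.102
#' @export
project_noshow_rate <- function(nsp_i, p_r) {
  check_proportion(nsp_i, "nsp_i")
  check_proportion(p_r, "p_r")
  (1 - p_r) * nsp_i
}

#' Full cost-effectiveness summary of a confusion matrix
#'
#' @param cc a `confusion_counts` object.
#' @return An object of class `ce_metrics`: list with `P_C`, `NSP_i`,
#'   `NSP_f`, `P_R`, `m1`, `m2` (the latter three `NA_real_` where
#'   undefined).
#' @export
ce_metrics <- function(cc) {
  check_n(cc)
  rates <- noshow_rates(cc)
  p_r <- suppressWarnings(reduction(cc))
  p_c <- proportion_actions(cc)
  out <- list(
    P_C = p_c,
    NSP_i = unname(rates["NSP_i"]),
    NSP_f = unname(rates["NSP_f"]),
    P_R = p_r,
    m1 = if (is.na(p_r) || p_c == 0) NA_real_ else p_r / p_c,
    m2 = if (is.na(p_r)) NA_real_ else p_r * (1 - p_c),
    counts = cc
  )
  class(out) <- "ce_metrics"
  out
}

#' @export
print.ce_metrics <- function(x, digits = 2, ...) {
  cat("Cost-effectiveness metrics (N =", x$counts$N, ")\n")
  v <- c(P_C = x$P_C, NSP_i = x$NSP_i, NSP_f = x$NSP_f,
         P_R = x$P_R, m1 = x$m1, m2 = x$m2)
  print(round(v, digits))
  invisible(x)
}

#' Geometric mean and Matthews correlation coefficient
#'
#' Comparison metrics commonly used for imbalanced classification.
#' `geometric_mean()` is `sqrt(sensitivity * specificity)`;
#' `matthews_corr()` is the standard MCC. Degenerate margins (a zero row or
#' column in the confusion matrix) make MCC's denominator zero; by the usual
#' convention the value is then 0, reported with a warning.
#'
#' @param cc a `confusion_counts` object.
#' @return A single numeric value.
#' @export
geometric_mean <- function(cc) {
  check_n(cc)
  pos <- cc$TP + cc$FN
  neg <- cc$TN + cc$FP
  if (pos == 0L || neg == 0L) {
    warning("GM degenerate: one class absent; returning 0", call. = FALSE)
    return(0)
  }
  sqrt((cc$TP / pos) * (cc$TN / neg))
}

#' @rdname geometric_mean
#' @export
matthews_corr <- function(cc) {
  check_n(cc)
  tp <- as.numeric(cc$TP); fp <- as.numeric(cc$FP)
  fn <- as.numeric(cc$FN); tn <- as.numeric(cc$TN)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) {
    warning("MCC degenerate margins; returning 0", call. = FALSE)
    return(0)
  }
  (tp * tn - fp * fn) / denom
}

#' Rank-based AUC of predicted probabilities
#'
#' Area under the ROC curve computed via the Mann-Whitney statistic with
#' midranks for ties: the probability that a randomly chosen no-show gets a
#' higher score than a randomly chosen show.
#'
#' @param probs numeric vector of predicted no-show probabilities.
#' @param truth binary vector of outcomes (1 = no-show).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
auc_score <- function(probs, truth) {
  truth <- as_binary(truth, "truth")
  if (length(probs) != length(truth)) {
    stop("probs and truth must have the same length", call. = FALSE)
  }
  if (anyNA(probs)) stop("probs contains NA", call. = FALSE)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires both classes present", call. = FALSE)
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
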