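# Evaluation layer: feature-outcome correlations, Gini importances, and
# the randomized reminder-trial analysis with its conversion to the
# cost-effectiveness metrics.

#' Randomize flagged appointments into control and intervention arms
#'
#' Simple random split as equal as possible: `floor(n/2)` control,
#' `ceiling(n/2)` intervention. Deterministic given the seed.
#'
#' @param flagged data.frame of flagged appointments (or any vector).
#' @param seed integer seed.
#' @return list with `control` and `intervention` (same type as the
#'   input).
#' @export
assign_arms <- function(flagged, seed = 1L) {
  n <- if (is.data.frame(flagged)) nrow(flagged) else length(flagged)
  if (n < 2L) stop("need at least 2 flagged appointments", call. = FALSE)
  set.seed(seed)
  control_idx <- sort(sample(n, n %/% 2L))
  pick <- function(i) {
    if (is.data.frame(flagged)) flagged[i, , drop = FALSE] else flagged[i]
  }
  list(control = pick(control_idx), intervention = pick(-control_idx))
}

#' Effect of a reminder intervention on no-show rates
#'
#' Compares the no-show rate of a control arm (no reminder) against an
#' intervention arm (reminder call), reporting the percentage-point
#' reduction and a two-sided significance test: a pooled two-proportion
#' z-test by default, or Fisher's exact / chi-squared test.
#'
#' @param control binary outcomes of the control arm (1 = no-show).
#' @param intervention binary outcomes of the intervention arm.
#' @param test `"z"`, `"fisher"` or `"chisq"`.
#' @return An object of class `trial_result`: arm sizes and rates,
#'   `reduction_pp` (percentage points), and `p_value`.
#' @export
trial_effect <- function(control, intervention,
                         test = c("z", "fisher", "chisq")) {
  test <- match.arg(test)
  control <- as_binary(control, "control")
  intervention <- as_binary(intervention, "intervention")
  if (length(control) == 0L || length(intervention) == 0L) {
    stop("both arms must be nonempty", call. = FALSE)
  }
  n1 <- length(control); n2 <- length(intervention)
  x1 <- sum(control); x2 <- sum(intervention)
  r1 <- x1 / n1; r2 <- x2 / n2
  p_value <- switch(test,
    z = {
      pool <- (x1 + x2) / (n1 + n2)
      se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
      if (se == 0) 1 else 2 * stats::pnorm(-abs((r1 - r2) / se))
    },
    fisher = stats::fisher.test(
      matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2))$p.value,
    chisq = stats::prop.test(c(x1, x2), c(n1, n2),
                             correct = FALSE)$p.value
  )
  structure(
    list(n_control = n1, n_intervention = n2,
         noshow_rate_control = r1, noshow_rate_intervention = r2,
         reduction_pp = 100 * (r1 - r2), p_value = p_value, test = test),
    class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Reminder-trial result\n")
  cat(sprintf("  control:      n = %d, no-show %.1f%%\n", x$n_control,
              100 * x$noshow_rate_control))
  cat(sprintf("  intervention: n = %d, no-show %.1f%%\n", x$n_intervention,
              100 * x$noshow_rate_intervention))
  cat(sprintf("  reduction: %.1f percentage points (p = %.3g, %s test)\n",
              x$reduction_pp, x$p_value, x$test))
  invisible(x)
}

#' Convert trial rates into cost-effectiveness metrics
#'
#' Uses the control arm's no-show rate as the proxy for the pre-existing
#' rate NSP_i: `P_R = 1 - rate_intervention / rate_control` and
#' `P_C = n_contacted / n_total`, then m1 and m2 from those proportions.
#' When `digits` is given, P_R and P_C are rounded to that many decimals
#' *before* forming m1 and m2 — the convention used when reporting from
#' two-decimal rates.
#'
#' @param rate_control,rate_intervention arm no-show proportions.
#' @param n_contacted number of appointments contacted.
#' @param n_total total analyzed appointments.
#' @param digits optional rounding of P_R and P_C before the ratio.
#' @return list with `P_R`, `P_C`, `m1`, `m2`, `reduction_pp`.
#' @examples
#' trial_to_ce(0.210, 0.107, n_contacted = 247, n_total = 4617, digits = 2)
#' @export
trial_to_ce <- function(rate_control, rate_intervention, n_contacted,
                        n_total, digits = NULL) {
  check_proportion(rate_control, "rate_control")
  check_proportion(rate_intervention, "rate_intervention")
  if (rate_control == 0) {
    warning("control no-show rate is 0: P_R undefined", call. = FALSE)
    return(list(P_R = NA_real_, P_C = n_contacted / n_total,
                m1 = NA_real_, m2 = NA_real_, reduction_pp = NA_real_))
  }
  if (n_total < n_contacted || n_contacted < 0) {
    stop("need 0 <= n_contacted <= n_total", call. = FALSE)
  }
  p_r <- 1 - rate_intervention / rate_control
  p_c <- n_contacted / n_total
  if (!is.null(digits)) {
    p_r <- round(p_r, digits)
    p_c <- round(p_c, digits)
  }
  list(
    P_R = p_r, P_C = p_c,
    m1 = if (p_c == 0) NA_real_ else p_r / p_c,
    m2 = p_r * (1 - p_c),
    reduction_pp = 100 * (rate_control - rate_intervention)
  )
}

#' Simulate the behavioral response to a reminder
#'
#' Models a reminder call as converting each would-be no-show into an
#' attendance independently with probability `conversion`; shows are
#' unaffected. Used to build fully synthetic trials.
#'
#' @param outcomes binary would-be outcomes (1 = no-show).
#' @param conversion probability a contacted no-show attends instead.
#' @param seed integer seed.
#' @return Binary vector of realized outcomes under intervention.
#' @export
simulate_intervention <- function(outcomes, conversion = 0.7, seed = 1L) {
  outcomes <- as_binary(outcomes, "outcomes")
  check_proportion(conversion, "conversion")
  set.seed(seed)
  converted <- outcomes == 1L & stats::runif(length(outcomes)) < conversion
  as.integer(outcomes == 1L & !converted)
}

#' Pearson correlation of every encoded feature with the outcome
#'
#' Point-biserial (Pearson) correlation per feature column with a two-sided
#' t-test p-value, sorted by absolute correlation. Constant columns are
#' reported with `NA` correlation rather than dropped silently.
#'
#' @param x encoded feature matrix (see [encode_features()]).
#' @param y binary outcome vector.
#' @return data.frame with `feature`, `r`, `p_value`, ordered by `|r|`
#'   descending.
#' @export
feature_correlations <- function(x, y) {
  y <- as_binary(y, "y")
  if (nrow(x) < 3L) stop("need at least 3 rows", call. = FALSE)
  if (stats::sd(y) == 0) stop("outcome is constant", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("all feature columns constant", call. = FALSE)
  n <- nrow(x)
  r <- rep(NA_real_, ncol(x))
  r[sds > 0] <- suppressWarnings(
    as.vector(stats::cor(x[, sds > 0, drop = FALSE], y)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(feature = colnames(x), r = r, p_value = p,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r), na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gini (mean decrease impurity) feature importances
#'
#' Impurity-based importances of a tree-ensemble model, normalized to sum
#' to 1 and sorted descending. For the rpart-based ensembles the per-tree
#' importances are aggregated (weighted by the boosting coefficients where
#' applicable). Requesting importances from a non-tree model is an error
#' suggesting the coefficient-based alternative.
#'
#' @param model a `noshow_model` or `noshow_classifier`.
#' @return data.frame with `feature` and `importance` (sums to 1),
#'   descending.
#' @export
gini_importances <- function(model) {
  clf <- if (inherits(model, "noshow_model")) model$classifier else model
  if (!inherits(clf, "noshow_classifier")) {
    stop("model must be a noshow_model or noshow_classifier",
         call. = FALSE)
  }
  feats <- clf$feature_names
  imp <- stats::setNames(numeric(length(feats)), feats)
  add_rpart <- function(tree, weight = 1) {
    vi <- tree$variable.importance
    if (is.null(vi)) return()
    pos <- as.integer(sub("^f", "", names(vi)))
    imp[feats[pos]] <<- imp[feats[pos]] + weight * vi
  }
  switch(clf$algorithm,
    random_forest = ,
    balanced_random_forest = {
      vi <- clf$fit$variable.importance
      imp[names(vi)] <- vi
    },
    adaboost = ,
    rusboost = {
      for (i in seq_along(clf$fit$trees)) {
        add_rpart(clf$fit$trees[[i]], clf$fit$alphas[i])
      }
    },
    balanced_bagging = for (b in clf$fit) add_rpart(b$tree),
    easy_ensemble = {
      for (b in clf$fit) {
        for (i in seq_along(b$trees)) add_rpart(b$trees[[i]], b$alphas[i])
      }
    },
    stop("Gini importance requires a tree-based model; for '",
         clf$algorithm, "' use coefficient magnitudes (coef()) instead",
         call. = FALSE)
  )
  imp <- pmax(imp, 0)
  if (sum(imp) == 0) {
    stop("model has no splits; importances undefined", call. = FALSE)
  }
  imp <- imp / sum(imp)
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
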