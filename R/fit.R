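# The main modelling entry point: per-specialty (or pooled) predictive
# models built by the three-stage selection pipeline, evaluated on a
# held-out test subset, returned as a classed object with the usual
# modelling methods.

#' Fit cost-effectiveness-selected no-show models
#'
#' For every specialty with enough labeled appointments, builds a
#' *predictive model* — the tuple (hyperparameters, algorithm,
#' classification threshold) plus its fitted state — by:
#' hyperparameter grid search per roster algorithm (3-fold CV maximizing
#' m2 at the 0.5 threshold), threshold tuning over `{0, 0.01, ..., 1}` on
#' out-of-fold probabilities, and final selection among the per-algorithm
#' finalists by 10-fold cross-validated m1. The winner is refit on the
#' full training subset and evaluated on the held-out test subset.
#'
#' With `pooled = TRUE` a single model is fit on all specialties jointly,
#' with one indicator column per specialty in the feature matrix — the
#' baseline architecture the per-specialty models are compared against.
#'
#' Historical no-show features are computed causally on the full record set
#' before splitting (they only ever look strictly backwards in time);
#' encoding vocabularies and numeric scaling are learned on the training
#' rows only and frozen in the model's feature schema.
#'
#' @param records labeled schedule data.frame (see [generate_schedule()]).
#' @param roster algorithms to consider, a subset of [algorithm_roster()].
#' @param grids named list of hyperparameter grids, as [default_grids()].
#' @param profile grid profile used when `grids` is `NULL`.
#' @param pooled fit one pooled model with specialty indicators instead of
#'   per-specialty models.
#' @param split_fraction training fraction of the stratified split.
#' @param cv_search folds for the hyperparameter search (default 3).
#' @param cv_select folds for the final selection (default 10).
#' @param threshold_step threshold sweep step (default 0.01).
#' @param threshold_objective objective of the threshold sweep, `"m2"`
#'   (default) or `"m1"`.
#' @param delay reservation-delay representation, `"numeric"` or
#'   `"binned"` (see [encode_features()]).
#' @param min_records minimum appointments per specialty.
#' @param seed integer seed controlling the split, folds and fits.
#' @return An object of class `noshow_fit`: list with `models` (named list
#'   of `noshow_model` objects), `report` (test-set Table-of-performance
#'   data.frame: specialty, algorithm, threshold, P_C, NSP_i, NSP_f, P_R,
#'   m1, m2, AUC, n_test), `selection` (per-specialty finalist CV
#'   reports), `skipped`, and the call configuration.
#' @examples
#' \donttest{
#' sched <- generate_schedule(sim_config(n_patients = 600,
#'                                       n_specialties = 2, seed = 3))
#' fit <- noshow_fit(sched, roster = "logistic_regression", seed = 3)
#' summary(fit)
#' }
#' @export
noshow_fit <- function(records,
                       roster = algorithm_roster(),
                       grids = NULL,
                       profile = c("fast", "full"),
                       pooled = FALSE,
                       split_fraction = 0.8,
                       cv_search = 3L,
                       cv_select = 10L,
                       threshold_step = 0.01,
                       threshold_objective = c("m2", "m1"),
                       delay = c("numeric", "binned"),
                       min_records = 20L,
                       seed = 1L) {
  profile <- match.arg(profile)
  threshold_objective <- match.arg(threshold_objective)
  delay <- match.arg(delay)
  roster <- match.arg(roster, algorithm_roster(), several.ok = TRUE)
  if (is.null(grids)) grids <- default_grids(profile)
  validate_schedule(records, require_outcome = TRUE)

  work <- records
  if (pooled) work$specialty_group <- "pooled" else
    work$specialty_group <- work$specialty

  split <- split_train_test_grouped(work, split_fraction, seed, min_records)
  groups <- sort(unique(split$train$specialty_group))

  models <- list()
  selection <- list()
  report_rows <- list()
  for (g in groups) {
    tr <- split$train[split$train$specialty_group == g, , drop = FALSE]
    te <- split$test[split$test$specialty_group == g, , drop = FALSE]
    sub <- rbind(tr, te)
    raw <- derive_raw_features(sub)
    is_train <- seq_len(nrow(sub)) <= nrow(tr)
    schema <- learn_schema(raw[is_train, , drop = FALSE], delay,
                           include_specialty = pooled)
    x_all <- apply_schema(raw, schema)
    x_tr <- x_all[is_train, , drop = FALSE]
    x_te <- x_all[!is_train, , drop = FALSE]
    y_tr <- sub$outcome[is_train]
    y_te <- sub$outcome[!is_train]

    finalists <- list()
    for (alg in roster) {
      gs <- grid_search(x_tr, y_tr, alg, grids[[alg]], k = cv_search,
                        seed = seed)
      tt <- tune_threshold(gs$oof, y_tr, gs$folds,
                           objective = threshold_objective,
                           step = threshold_step)
      finalists[[alg]] <- list(algorithm = alg, params = gs$best_params,
                               threshold = tt$threshold,
                               search_m2 = gs$best_m2)
    }
    sel <- select_best(x_tr, y_tr, unname(finalists), k = cv_select,
                       seed = seed)
    model <- structure(
      list(specialty = g, algorithm = sel$classifier$algorithm,
           hyperparameters = sel$classifier$params,
           threshold = sel$threshold, classifier = sel$classifier,
           schema = schema, pooled = pooled),
      class = "noshow_model")
    models[[g]] <- model
    selection[[g]] <- sel$report

    probs <- predict_prob(sel$classifier, x_te)
    cc <- confusion_counts(y_te, as.integer(probs >= sel$threshold))
    cem <- ce_metrics(cc)
    report_rows[[g]] <- data.frame(
      specialty = g, algorithm = model$algorithm,
      threshold = model$threshold, P_C = cem$P_C, NSP_i = cem$NSP_i,
      NSP_f = cem$NSP_f, P_R = cem$P_R, m1 = cem$m1, m2 = cem$m2,
      AUC = auc_score(probs, y_te), n_test = length(y_te),
      stringsAsFactors = FALSE)
  }
  structure(
    list(models = models,
         report = do.call(rbind, c(report_rows, make.row.names = FALSE)),
         selection = selection, skipped = split$skipped, pooled = pooled,
         roster = roster, delay = delay, seed = seed),
    class = "noshow_fit")
}

# split on a precomputed grouping column (specialty or pooled)
split_train_test_grouped <- function(records, fraction, seed, min_records) {
  set.seed(seed)
  skipped <- character(0)
  train_idx <- logical(nrow(records))
  keep <- logical(nrow(records))
  for (g in sort(unique(records$specialty_group))) {
    rows <- which(records$specialty_group == g)
    y <- records$outcome[rows]
    if (length(rows) < min_records || length(unique(y)) < 2L) {
      warning("group '", g, "' skipped: fewer than ", min_records,
              " records or a single outcome class", call. = FALSE)
      skipped <- c(skipped, g)
      next
    }
    keep[rows] <- TRUE
    for (cls in c(0L, 1L)) {
      ridx <- rows[y == cls]
      n_tr <- round(fraction * length(ridx))
      n_tr <- min(max(n_tr, 1L), length(ridx) - 1L)
      train_idx[sample(ridx, n_tr)] <- TRUE
    }
  }
  list(train = records[keep & train_idx, , drop = FALSE],
       test = records[keep & !train_idx, , drop = FALSE],
       skipped = skipped)
}

#' @export
print.noshow_fit <- function(x, ...) {
  cat("No-show predictive models (",
      if (x$pooled) "pooled" else "per-specialty", ")\n", sep = "")
  cat(" groups modelled:", length(x$models),
      if (length(x$skipped)) paste0("(skipped: ",
                                    paste(x$skipped, collapse = ", "), ")"),
      "\n")
  for (m in x$models) {
    cat(sprintf("  %-22s %s @ threshold %.2f\n", m$specialty, m$algorithm,
                m$threshold))
  }
  invisible(x)
}

#' @export
summary.noshow_fit <- function(object, digits = 2, ...) {
  out <- object$report
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = digits)
  out
}

#' @export
coef.noshow_fit <- function(object, specialty = NULL, ...) {
  models <- if (is.null(specialty)) object$models else
    object$models[specialty]
  lapply(models, coef)
}

#' @export
coef.noshow_model <- function(object, ...) {
  if (object$algorithm != "logistic_regression") {
    stop("coefficients are only defined for logistic_regression models; ",
         "use gini_importances() for tree ensembles", call. = FALSE)
  }
  cf <- as.matrix(stats::coef(object$classifier$fit))
  stats::setNames(cf[, 1], rownames(cf))
}

#' @export
print.noshow_model <- function(x, ...) {
  cat("No-show predictive model —", x$specialty, "\n")
  cat(" algorithm:", x$algorithm, "\n")
  hp <- x$hyperparameters
  cat(" hyperparameters:",
      paste(names(hp), vapply(hp, format, character(1)), sep = "=",
            collapse = ", "), "\n")
  cat(" threshold:", format(x$threshold), "(flag iff probability >= it)\n")
  invisible(x)
}

#' Predict no-show probabilities for new appointments
#'
#' @param object a `noshow_model`.
#' @param newdata schedule data.frame (outcome optional) or an encoded
#'   feature matrix matching the model's schema.
#' @param ... unused.
#' @return Numeric vector of no-show probabilities, named by appointment id
#'   when `newdata` is a schedule.
#' @export
predict.noshow_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    return(predict_prob(object$classifier, newdata))
  }
  raw <- derive_raw_features(newdata)
  x <- apply_schema(raw, object$schema)
  stats::setNames(predict_prob(object$classifier, x),
                  newdata$appointment_id)
}

#' Predict from a set of fitted no-show models
#'
#' @param object a `noshow_fit`.
#' @param newdata schedule data.frame.
#' @param type `"prob"` for a vector of probabilities (NA for appointments
#'   of unmodelled specialties) or `"ranked"` for a ranked call list (see
#'   [rank_appointments()]).
#' @param ... unused.
#' @export
predict.noshow_fit <- function(object, newdata,
                               type = c("prob", "ranked"), ...) {
  type <- match.arg(type)
  if (type == "ranked") return(rank_appointments(object, newdata))
  probs <- rep(NA_real_, nrow(newdata))
  groups <- if (object$pooled) rep("pooled", nrow(newdata)) else
    newdata$specialty
  for (g in intersect(unique(groups), names(object$models))) {
    sel <- groups == g
    probs[sel] <- predict(object$models[[g]],
                          newdata[sel, , drop = FALSE])
  }
  stats::setNames(probs, newdata$appointment_id)
}

#' @export
plot.noshow_fit <- function(x, metric = "m1", ...) {
  rep <- x$report
  graphics::barplot(stats::setNames(rep[[metric]], rep$specialty),
                    las = 2, ylab = metric,
                    main = "Test-set cost-effectiveness by specialty", ...)
  invisible(x)
}
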