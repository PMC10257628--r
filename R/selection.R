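# Three-stage per-specialty model construction:
#   1. per-algorithm hyperparameter grid search, 3-fold CV, maximizing m2
#      at the default 0.5 threshold;
#   2. classification-threshold tuning on out-of-fold probabilities over
#      the grid {0.00, 0.01, ..., 1.00};
#   3. best-model selection among the (algorithm, hyperparameters,
#      threshold) finalists by 10-fold cross-validated m1.
# All tie-breaks are deterministic: first-listed grid point, lowest
# threshold, then higher m2 and roster order among finalists.

#' Hyperparameter grids
#'
#' `profile = "full"` ships the faithful search grids for all eight
#' algorithms; `profile = "fast"` is a desk-scale profile with one small,
#' sensible configuration per algorithm (and a row cap for the SVM) so that
#' the full pipeline runs in minutes on a laptop.
#'
#' @param profile `"fast"` or `"full"`.
#' @return Named list (one entry per algorithm) of named lists of candidate
#'   values; the cartesian product forms the grid.
#' @export
default_grids <- function(profile = c("fast", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    rf <- list(bootstrap = c(TRUE, FALSE), max_features = c("auto", "sqrt"),
               n_estimators = seq(200, 2000, by = 200),
               max_depth = c(seq(10, 100, by = 10), NA),
               min_samples_split = c(2, 5, 10, 50))
    bag_n <- c(10, 50, 100, 200, 500, 1000, 1200, 1400, 1600, 1800)
    return(list(
      adaboost = list(max_depth = c(1, 2, 5, 8, 10, 15),
                      min_samples_leaf = c(2, 3, 5, 10, 20, 40),
                      n_estimators = c(50, 100, 200, 300, 500, 750, 1000),
                      learning_rate = c(0.01, 0.05, 0.1, 0.2)),
      random_forest = rf,
      balanced_random_forest = rf,
      svm = list(kernel = c("linear", "rbf"), C = c(1, 10, 100, 1000),
                 gamma = c(1, 0.1, 0.001, 0.0001)),
      logistic_regression = list(penalty = c("l1", "l2"),
                                 C = 10^seq(-5, 3)),
      rusboost = list(n_estimators = c(50, 100, 400, 800, 1000, 1200,
                                       1400, 1600, 1800, 2000),
                      replacement = c(TRUE, FALSE)),
      balanced_bagging = list(bootstrap = c(TRUE, FALSE),
                              bootstrap_features = c(TRUE, FALSE),
                              replacement = c(TRUE, FALSE),
                              n_estimators = bag_n),
      easy_ensemble = list(replacement = c(TRUE, FALSE),
                           n_estimators = bag_n)
    ))
  }
  list(
    adaboost = list(max_depth = 2, min_samples_leaf = 10,
                    n_estimators = 50, learning_rate = 0.1),
    random_forest = list(bootstrap = TRUE, max_features = "sqrt",
                         n_estimators = 100, max_depth = NA,
                         min_samples_split = 10),
    balanced_random_forest = list(bootstrap = TRUE, max_features = "sqrt",
                                  n_estimators = 100, max_depth = NA,
                                  min_samples_split = 10),
    svm = list(kernel = "linear", C = 1, max_rows = 1000),
    logistic_regression = list(penalty = "l2", C = 1),
    rusboost = list(n_estimators = 50, replacement = FALSE),
    balanced_bagging = list(n_estimators = 25),
    easy_ensemble = list(n_estimators = 5, boost_rounds = 10)
  )
}

expand_param_grid <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  combos <- expand.grid(lapply(grid, seq_along), KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    stats::setNames(
      lapply(names(grid), function(nm) grid[[nm]][[combos[i, nm]]]),
      names(grid))
  })
}

#' Stratified cross-validation folds
#'
#' Assigns each observation to one of `k` folds, preserving the class
#' balance: within each class, observations are shuffled and dealt
#' round-robin. Deterministic given `seed`.
#'
#' @param y binary outcome vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified train/test split per specialty
#'
#' Splits each specialty's appointments into training and testing subsets,
#' stratified by outcome. Specialties with fewer than `min_records`
#' appointments, or with a single outcome class, are excluded with a
#' warning rather than modelled.
#'
#' @param records labeled schedule data.frame.
#' @param fraction training fraction.
#' @param seed integer seed.
#' @param min_records minimum appointments for a specialty to be modelled.
#' @return list with data.frames `train` and `test` (the `specialty` column
#'   identifies the subsets) and `skipped`, a character vector of excluded
#'   specialties.
#' @export
split_train_test <- function(records, fraction = 0.8, seed = 1L,
                             min_records = 20L) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie in (0, 1)", call. = FALSE)
  }
  validate_schedule(records, require_outcome = TRUE)
  set.seed(seed)
  skipped <- character(0)
  train_idx <- logical(nrow(records))
  keep <- logical(nrow(records))
  for (sp in sort(unique(records$specialty))) {
    rows <- which(records$specialty == sp)
    y <- records$outcome[rows]
    if (length(rows) < min_records || length(unique(y)) < 2L) {
      warning("specialty '", sp, "' skipped: fewer than ", min_records,
              " records or a single outcome class", call. = FALSE)
      skipped <- c(skipped, sp)
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

# cross-validated metrics of one candidate; returns the per-fold metric
# values plus out-of-fold probabilities
cv_candidate <- function(x, y, algorithm, params, folds, threshold = 0.5,
                         seed = 1L) {
  k <- max(folds)
  oof <- rep(NA_real_, length(y))
  m1s <- m2s <- aucs <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    hold <- folds == j
    clf <- fit_classifier(algorithm, x[!hold, , drop = FALSE], y[!hold],
                          params, seed = seed + j)
    p <- predict_prob(clf, x[hold, , drop = FALSE])
    oof[hold] <- p
    yh <- y[hold]
    if (sum(yh == 1L) == 0L || sum(yh == 0L) == 0L) next  # degenerate fold
    cc <- confusion_counts(yh, as.integer(p >= threshold))
    m1s[j] <- suppressWarnings(metric_m1(cc))
    m2s[j] <- suppressWarnings(metric_m2(cc))
    aucs[j] <- auc_score(p, yh)
  }
  list(oof = oof,
       m1 = if (all(is.na(m1s))) NA_real_ else mean(m1s, na.rm = TRUE),
       m2 = if (all(is.na(m2s))) NA_real_ else mean(m2s, na.rm = TRUE),
       auc = if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE))
}

#' Hyperparameter grid search maximizing cross-validated m2
#'
#' Evaluates every point of the algorithm's grid by k-fold cross-validation
#' (default 3-fold), scoring mean out-of-fold m2 at the default 0.5
#' threshold, and returns the argmax. Folds where the held-out data contain
#' no actual no-shows contribute no score. Ties are broken by the
#' first-listed grid point.
#'
#' @param x encoded training feature matrix.
#' @param y binary training outcomes.
#' @param algorithm one of [algorithm_roster()].
#' @param grid named list of candidate values (see [default_grids()]).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @param threshold classification threshold used during the search.
#' @return list with `best_params`, `best_m2`, `oof` (out-of-fold
#'   probabilities of the best point), `folds`, and `results` (one row per
#'   grid point with its mean CV m2).
#' @export
grid_search <- function(x, y, algorithm, grid, k = 3L, seed = 1L,
                        threshold = 0.5) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  candidates <- expand_param_grid(grid)
  folds <- stratified_folds(y, k, seed)
  best <- NULL
  scores <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    res <- cv_candidate(x, y, algorithm, candidates[[i]], folds,
                        threshold = threshold, seed = seed)
    scores[i] <- res$m2
    if (!is.na(res$m2) && (is.null(best) || res$m2 > best$m2)) {
      best <- list(params = candidates[[i]], m2 = res$m2, oof = res$oof)
    }
  }
  if (is.null(best)) {
    stop("all grid points degenerate for algorithm '", algorithm, "'",
         call. = FALSE)
  }
  list(best_params = best$params, best_m2 = best$m2, oof = best$oof,
       folds = folds,
       results = data.frame(point = seq_along(candidates), m2 = scores))
}

#' Tune the classification threshold on out-of-fold probabilities
#'
#' Sweeps thresholds over `{0, step, 2*step, ..., 1}` and returns the one
#' maximizing the mean out-of-fold objective (m2 by default, m1
#' optionally). Ties are resolved toward the lowest threshold. If the
#' scorer is uninformative (constant probabilities) the result is flagged
#' `degenerate`.
#'
#' @param probs out-of-fold predicted probabilities.
#' @param y binary outcomes aligned with `probs`.
#' @param folds fold ids used to produce `probs` (objective is averaged
#'   across folds).
#' @param objective `"m2"` or `"m1"`.
#' @param step threshold grid step (default 0.01).
#' @return list with `threshold`, `objective_value`, `objective`,
#'   `degenerate` flag, and the full `sweep` data.frame.
#' @export
tune_threshold <- function(probs, y, folds = rep(1L, length(y)),
                           objective = c("m2", "m1"), step = 0.01) {
  objective <- match.arg(objective)
  if (length(probs) != length(y)) {
    stop("probs and y must align", call. = FALSE)
  }
  thresholds <- seq(0, 1, by = step)
  metric_fun <- if (objective == "m2") metric_m2 else metric_m1
  k <- max(folds)
  sweep <- vapply(thresholds, function(t) {
    vals <- vapply(seq_len(k), function(j) {
      hold <- folds == j
      cc <- confusion_counts(y[hold], as.integer(probs[hold] >= t))
      suppressWarnings(metric_fun(cc))
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  if (all(is.na(sweep))) {
    stop("objective undefined at every threshold", call. = FALSE)
  }
  best <- which.max(replace(sweep, is.na(sweep), -Inf))  # lowest-t tie win
  list(threshold = thresholds[best], objective_value = sweep[best],
       objective = objective,
       degenerate = length(unique(probs)) == 1L,
       sweep = data.frame(threshold = thresholds, value = sweep))
}

#' Select the best predictive model among finalists by 10-fold CV m1
#'
#' Each finalist — a complete (algorithm, hyperparameters, threshold)
#' candidate — is evaluated by k-fold cross-validation on the training
#' data, recording mean out-of-fold m1, m2 and AUC at the finalist's own
#' threshold. The winner maximizes mean m1; ties fall to the higher m2 and
#' then to roster order. The winner is refit on the full training data.
#'
#' @param x encoded training feature matrix.
#' @param y binary training outcomes.
#' @param finalists list of lists with fields `algorithm`, `params`,
#'   `threshold`.
#' @param k folds for the selection CV (default 10).
#' @param seed integer seed.
#' @return list with `classifier` (refit winner), `winner` (index into
#'   `finalists`), `threshold`, and `report` (one row per finalist with CV
#'   m1/m2/AUC).
#' @export
select_best <- function(x, y, finalists, k = 10L, seed = 1L) {
  if (length(finalists) == 0L) stop("no finalists", call. = FALSE)
  folds <- stratified_folds(y, k, seed)
  roster <- algorithm_roster()
  rows <- lapply(finalists, function(f) {
    res <- cv_candidate(x, y, f$algorithm, f$params, folds,
                        threshold = f$threshold, seed = seed)
    data.frame(algorithm = f$algorithm, threshold = f$threshold,
               cv_m1 = res$m1, cv_m2 = res$m2, cv_auc = res$auc)
  })
  report <- do.call(rbind, rows)
  ok <- !is.na(report$cv_m1)
  if (!any(ok)) stop("all finalists invalid (m1 undefined)", call. = FALSE)
  m1key <- replace(report$cv_m1, !ok, -Inf)
  m2key <- replace(report$cv_m2, is.na(report$cv_m2), -Inf)
  ord <- order(-m1key, -m2key, match(report$algorithm, roster))
  winner <- ord[1]
  f <- finalists[[winner]]
  clf <- fit_classifier(f$algorithm, x, y, f$params, seed = seed)
  list(classifier = clf, winner = winner, threshold = f$threshold,
       report = report)
}
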