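# Classifier roster.
#
# Eight probabilistic classifiers, four of them designed for imbalanced
# data. Random Forest and Balanced Random Forest delegate to ranger (the
# balanced variant under-samples the majority class within every bootstrap
# via class-wise sampling fractions); logistic regression delegates to
# glmnet; the SVM delegates to e1071 with a Platt sigmoid mapping decision
# values to probabilities. AdaBoost, RUSBoost, Balanced Bagging and Easy
# Ensemble are implemented here on rpart base learners following their
# published definitions.

#' Algorithm roster
#'
#' The eight candidate algorithms in their canonical order (the order is
#' also the final tie-break in model selection).
#'
#' @return Character vector of algorithm identifiers.
#' @export
algorithm_roster <- function() {
  c("rusboost", "balanced_random_forest", "balanced_bagging",
    "easy_ensemble", "logistic_regression", "random_forest", "adaboost",
    "svm")
}

default_params <- function(algorithm) {
  switch(algorithm,
    adaboost = list(max_depth = 1, min_samples_leaf = 2, n_estimators = 50,
                    learning_rate = 0.1),
    rusboost = list(max_depth = 1, n_estimators = 50, replacement = FALSE,
                    learning_rate = 0.1),
    random_forest = list(bootstrap = TRUE, max_features = "sqrt",
                         n_estimators = 200, max_depth = NA,
                         min_samples_split = 2),
    balanced_random_forest = list(bootstrap = TRUE, max_features = "sqrt",
                                  n_estimators = 200, max_depth = NA,
                                  min_samples_split = 2),
    balanced_bagging = list(bootstrap = TRUE, bootstrap_features = FALSE,
                            replacement = TRUE, n_estimators = 50),
    easy_ensemble = list(replacement = FALSE, n_estimators = 10,
                         boost_rounds = 10),
    logistic_regression = list(penalty = "l2", C = 1),
    svm = list(kernel = "linear", C = 1, gamma = 0.1, max_rows = Inf),
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

# positional, syntactic column names for rpart data frames
as_rpart_df <- function(x) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df
}

rpart_weak <- function(df, y, w, max_depth, min_leaf = 2) {
  df$.y <- factor(y, levels = c(0, 1))
  rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
               control = rpart::rpart.control(
                 maxdepth = max_depth, minbucket = min_leaf,
                 minsplit = max(2 * min_leaf, 2), cp = 0, xval = 0,
                 maxcompete = 0, maxsurrogate = 0))
}

# discrete AdaBoost (SAMME with two classes) on rpart trees
boost_fit <- function(df, y, max_depth, min_leaf, rounds, learning_rate,
                      sampler = NULL) {
  n <- nrow(df)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(rounds)) {
    if (is.null(sampler)) {
      tree <- rpart_weak(df, y, w * n, max_depth, min_leaf)
    } else {
      idx <- sampler(w)
      wi <- w[idx] / sum(w[idx])
      tree <- rpart_weak(df[idx, , drop = FALSE], y[idx], wi * length(idx),
                         max_depth, min_leaf)
    }
    pred <- as.integer(predict(tree, df, type = "class") == "1")
    err <- sum(w * (pred != y))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- learning_rate * log((1 - err) / err)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (length(trees) == 0L) {
    # no weak learner beat chance: fall back to the prior
    return(list(trees = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(trees = trees, alphas = alphas, prior = mean(y))
}

boost_prob <- function(fit, df) {
  if (length(fit$trees) == 0L) return(rep(fit$prior, nrow(df)))
  votes <- vapply(fit$trees, function(tr) {
    as.numeric(predict(tr, df, type = "class") == "1")
  }, numeric(nrow(df)))
  if (nrow(df) == 1L) votes <- matrix(votes, nrow = 1L)
  drop(votes %*% fit$alphas) / sum(fit$alphas)
}

# balanced index: all of the minority class plus an equal-size draw of the
# majority (the under-sampling step shared by RUSBoost / Easy Ensemble /
# Balanced Bagging)
balanced_index <- function(y, replace_minority = FALSE,
                           majority_replace = FALSE) {
  i1 <- which(y == 1L)
  i0 <- which(y == 0L)
  if (length(i1) == 0L || length(i0) == 0L) {
    stop("both classes required to fit a classifier", call. = FALSE)
  }
  minority <- if (length(i1) <= length(i0)) i1 else i0
  majority <- if (length(i1) <= length(i0)) i0 else i1
  m <- if (replace_minority) {
    sample(minority, length(minority), replace = TRUE)
  } else {
    minority
  }
  k <- sample(majority, min(length(minority), length(majority)),
              replace = majority_replace)
  sort(c(m, k))
}

#' Fit one classifier from the roster
#'
#' Low-level fitting interface used by the selection pipeline. `x` must be
#' an encoded feature matrix (see [encode_features()]); `y` the binary
#' outcome (1 = no-show).
#'
#' @param algorithm one of [algorithm_roster()].
#' @param x numeric feature matrix.
#' @param y binary outcome vector.
#' @param params named list of hyperparameters; missing entries take the
#'   algorithm's defaults (the shipped grids document the tested values).
#' @param seed integer seed; fits are deterministic given it.
#' @return An object of class `noshow_classifier` supporting
#'   [predict_prob()].
#' @export
fit_classifier <- function(algorithm, x, y, params = list(), seed = 1L) {
  algorithm <- match.arg(algorithm, algorithm_roster())
  y <- as_binary(y, "y")
  if (nrow(x) != length(y)) stop("x/y size mismatch", call. = FALSE)
  p <- utils::modifyList(default_params(algorithm), params)
  set.seed(seed)
  fit <- switch(algorithm,
    adaboost = {
      df <- as_rpart_df(x)
      boost_fit(df, y, p$max_depth, p$min_samples_leaf, p$n_estimators,
                p$learning_rate)
    },
    rusboost = {
      df <- as_rpart_df(x)
      rep_flag <- isTRUE(p$replacement)
      boost_fit(df, y, p$max_depth, 2, p$n_estimators, p$learning_rate,
                sampler = function(w) {
                  balanced_index(y, majority_replace = rep_flag)
                })
    },
    random_forest = ,
    balanced_random_forest = {
      nt <- p$n_estimators
      mtry <- if (identical(p$max_features, "sqrt")) {
        max(1L, floor(sqrt(ncol(x))))
      } else {
        max(1L, floor(ncol(x) / 3))  # "auto" fallback
      }
      args <- list(
        x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
        num.trees = nt, mtry = min(mtry, ncol(x)),
        min.node.size = max(1, p$min_samples_split %/% 2),
        max.depth = if (is.na(p$max_depth)) 0 else p$max_depth,
        replace = isTRUE(p$bootstrap), seed = seed, num.threads = 1,
        importance = "impurity", verbose = FALSE
      )
      if (algorithm == "balanced_random_forest") {
        n1 <- sum(y == 1L); n0 <- sum(y == 0L)
        frac <- min(n1, n0) / length(y)
        args$sample.fraction <- c(frac, frac)
        args$replace <- TRUE
      } else if (!args$replace) {
        args$sample.fraction <- 0.632
      }
      do.call(ranger::ranger, args)
    },
    balanced_bagging = {
      df <- as_rpart_df(x)
      nfeat <- ncol(x)
      lapply(seq_len(p$n_estimators), function(b) {
        idx <- balanced_index(y, replace_minority = isTRUE(p$bootstrap),
                              majority_replace = isTRUE(p$replacement))
        feats <- if (isTRUE(p$bootstrap_features)) {
          sort(sample(seq_len(nfeat), nfeat, replace = TRUE))
        } else {
          seq_len(nfeat)
        }
        dfi <- df[idx, unique(feats), drop = FALSE]
        dfi$.y <- factor(y[idx], levels = c(0, 1))
        list(tree = rpart::rpart(
          .y ~ ., data = dfi, method = "class",
          control = rpart::rpart.control(cp = 0.001, xval = 0,
                                         maxcompete = 0,
                                         maxsurrogate = 0)))
      })
    },
    easy_ensemble = {
      df <- as_rpart_df(x)
      lapply(seq_len(p$n_estimators), function(b) {
        idx <- balanced_index(y, majority_replace = isTRUE(p$replacement))
        boost_fit(df[idx, , drop = FALSE], y[idx], 1, 2, p$boost_rounds,
                  1.0)
      })
    },
    logistic_regression = {
      alpha <- if (identical(tolower(p$penalty), "l1")) 1 else 0
      lam <- 1 / (p$C * length(y))
      glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                     lambda = lam, standardize = FALSE)
    },
    svm = {
      idx <- seq_len(nrow(x))
      if (is.finite(p$max_rows) && nrow(x) > p$max_rows) {
        idx <- sort(c(
          sample(which(y == 1L), ceiling(p$max_rows * mean(y == 1L))),
          sample(which(y == 0L), floor(p$max_rows * mean(y == 0L)))
        ))
      }
      args <- list(x = x[idx, , drop = FALSE],
                   y = factor(y[idx], levels = c(0, 1)),
                   kernel = p$kernel, cost = p$C, scale = FALSE,
                   probability = FALSE)
      if (identical(p$kernel, "rbf")) {
        args$kernel <- "radial"
        args$gamma <- p$gamma
      }
      m <- do.call(e1071::svm, args)
      dv <- attr(predict(m, x[idx, , drop = FALSE],
                         decision.values = TRUE), "decision.values")[, 1]
      # quasi-separation here only sharpens the sigmoid; safe to ignore
      platt <- suppressWarnings(
        stats::glm.fit(cbind(1, dv), y[idx],
                       family = stats::binomial())$coefficients)
      list(svm = m, platt = platt)
    }
  )
  structure(list(algorithm = algorithm, params = p, fit = fit,
                 n_features = ncol(x), feature_names = colnames(x)),
            class = "noshow_classifier")
}

#' Predict no-show probabilities from a fitted classifier
#'
#' @param clf a `noshow_classifier` from [fit_classifier()].
#' @param x feature matrix with the same columns (order and count) as at
#'   fitting time.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(clf, x) {
  if (!inherits(clf, "noshow_classifier")) {
    stop("clf must be a noshow_classifier", call. = FALSE)
  }
  if (ncol(x) != clf$n_features) {
    stop("feature matrix has ", ncol(x), " columns; model expects ",
         clf$n_features, call. = FALSE)
  }
  switch(clf$algorithm,
    adaboost = ,
    rusboost = boost_prob(clf$fit, as_rpart_df(x)),
    random_forest = ,
    balanced_random_forest = {
      pr <- predict(clf$fit, data = x, num.threads = 1,
                    verbose = FALSE)$predictions
      unname(pr[, "1"])
    },
    balanced_bagging = {
      df <- as_rpart_df(x)
      probs <- vapply(clf$fit, function(b) {
        predict(b$tree, df, type = "prob")[, "1"]
      }, numeric(nrow(x)))
      if (nrow(x) == 1L) probs <- matrix(probs, nrow = 1L)
      rowMeans(probs)
    },
    easy_ensemble = {
      df <- as_rpart_df(x)
      probs <- vapply(clf$fit, function(b) boost_prob(b, df),
                      numeric(nrow(x)))
      if (nrow(x) == 1L) probs <- matrix(probs, nrow = 1L)
      rowMeans(probs)
    },
    logistic_regression = {
      drop(predict(clf$fit, newx = x, type = "response"))
    },
    svm = {
      dv <- attr(predict(clf$fit$svm, x, decision.values = TRUE),
                 "decision.values")[, 1]
      unname(stats::plogis(clf$fit$platt[1] + clf$fit$platt[2] * dv))
    }
  )
}
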