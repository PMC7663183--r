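# Linear-kernel support vector modelling (LibSVM via e1071): epsilon-SVR
# for HIC retention time, C-SVM for class labels. Hyperparameters are found
# by an exhaustive grid evaluated with repeated random k-fold CV; all fold
# assignments are seeded so the whole procedure is reproducible.

#' SVM grid-search configuration
#'
#' Defaults reproduce the reference grids: C over `10^(-5..4)` (10 values)
#' and, for regression, epsilon over `10^seq(-3, 1, 0.5)` (9 values) — 90
#' parameter permutations — evaluated by 5-fold CV repeated 20 times.
#'
#' @param mode `"epsilon_regression"` or `"c_classification"`.
#' @param cost_grid,epsilon_grid Hyperparameter grids (epsilon ignored for
#'   classification).
#' @param cv_folds,cv_repeats Repeated random k-fold settings.
#' @param seed RNG seed for the fold assignments.
#' @return An `svm_config` list.
#' @export
svm_config <- function(mode = c("epsilon_regression", "c_classification"),
                       cost_grid = 10^(-5:4),
                       epsilon_grid = 10^seq(-3, 1, by = 0.5),
                       cv_folds = 5, cv_repeats = 20, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(cv_folds >= 2, cv_repeats >= 1)
  structure(as.list(environment()), class = "svm_config")
}

# Seeded fold assignments: one shuffled balanced assignment per repeat.
.make_folds <- function(n, k, repeats, seed) {
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    sample(rep(seq_len(k), length.out = n))
  })
}

# Regression fits use the package's deterministic dual-coordinate-descent
# solver for the linear epsilon-insensitive problem (tolerance 1e-6); it is
# exact for the linear kernel and remains fast across the whole C grid,
# where generic SMO solvers stall at the largest C values. Classification
# stays on LibSVM (e1071). A degenerate classification fit (single class in
# a fold) falls back to the constant majority model it is equivalent to.
.fit_svm <- function(X, y, config, cost, epsilon = 0.1, max_sweeps = 20000) {
  if (config$mode == "epsilon_regression") {
    linear_svr_fit(X, y, cost = cost, epsilon = epsilon,
                   max_sweeps = max_sweeps)
  } else {
    tryCatch(
      e1071::svm(X, factor(y), type = "C-classification", kernel = "linear",
                 cost = cost, scale = FALSE),
      error = function(e) {
        tab <- table(y)
        structure(list(value = names(tab)[which.max(tab)]),
                  class = "fq_const_model")
      })
  }
}

#' @export
predict.fq_const_model <- function(object, newdata, ...) {
  rep(object$value, nrow(as.matrix(newdata)))
}

#' Linear epsilon-insensitive support vector regression
#'
#' Solves the linear-kernel epsilon-SVR problem exactly by deterministic
#' dual coordinate descent (cyclic sweeps over the box-constrained dual,
#' convergence tolerance 1e-6 on the projected gradient). The bias enters
#' as a weakly regularised augmented feature on the centred response, which
#' coincides with the usual formulation to well below the solver tolerance
#' in practice.
#'
#' @param X Predictor matrix (scaled upstream).
#' @param y Numeric response.
#' @param cost Box constraint C.
#' @param epsilon Insensitivity-tube half width (response units).
#' @param tol Convergence tolerance on the projected gradient.
#' @param max_sweeps Sweep budget; in the weakly regularised corner of the
#'   C grid the dual cycles long after the predictions have stabilised, so
#'   cross-validation fits run on a reduced budget (see Details in the
#'   methods vignette) while final refits use the full one.
#' @return An `fq_linear_svr` object with `weights` and `intercept`.
#' @export
linear_svr_fit <- function(X, y, cost = 1, epsilon = 0.1, tol = 1e-6,
                           max_sweeps = 20000) {
  X <- as.matrix(X)
  fit <- cpp_linear_svr(X, as.numeric(y), cost, epsilon, tol,
                        as.integer(max_sweeps))
  structure(list(weights = drop(fit$weights), intercept = fit$intercept,
                 cost = cost, epsilon = epsilon,
                 converged = fit$converged, sweeps = fit$sweeps),
            class = "fq_linear_svr")
}

#' @export
predict.fq_linear_svr <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$weights) + object$intercept
}

# Repeated-CV metrics for one hyperparameter pair; per repeat the held-out
# predictions are pooled, metrics computed, then averaged over repeats.
# Regression runs through the compiled CV loop; classification (10 grid
# points, not 90) stays on the R path over LibSVM.
.cv_eval <- function(X, y, config, cost, epsilon, folds) {
  if (config$mode == "epsilon_regression") {
    fm <- do.call(cbind, folds)
    out <- cpp_svr_cv(as.matrix(X), as.numeric(y), fm, cost, epsilon)
    return(list(rmse = mean(out$rmse), r2 = mean(out$r2)))
  }
  per_rep <- vapply(folds, function(fold) {
    pred <- if (config$mode == "epsilon_regression") numeric(length(y)) else
      character(length(y))
    for (f in unique(fold)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 && config$mode == "c_classification") {
        pred[!tr] <- as.character(y[tr][1]); next
      }
      m <- .fit_svm(X[tr, , drop = FALSE], y[tr], config, cost, epsilon,
                    max_sweeps = 500)
      p <- stats::predict(m, X[!tr, , drop = FALSE])
      pred[!tr] <- if (config$mode == "epsilon_regression") p else
        as.character(p)
    }
    if (config$mode == "epsilon_regression") {
      m <- qsar_metrics(y, as.numeric(pred), "regression")
      c(m$rmse, m$r2)
    } else {
      m <- qsar_metrics(y, pred, "classification")
      c(m$mcc, NA_real_)
    }
  }, c(0, 0))
  if (config$mode == "epsilon_regression") {
    list(rmse = mean(per_rep[1, ]), r2 = mean(per_rep[2, ]))
  } else {
    list(mcc = mean(per_rep[1, ]))
  }
}

#' Train an SVM over the hyperparameter grid
#'
#' Evaluates every grid point by repeated random k-fold CV on the
#' calibration set, picks the pair with the lowest mean CV RMSE (regression)
#' or highest mean CV MCC (classification; ties break to the smaller C,
#' then smaller epsilon), refits on the full calibration set, and reports
#' calibration / CV / test diagnostics. Descriptors are autoscaled with
#' calibration-derived parameters; the test set never influences scaling,
#' selection or tuning.
#'
#' @param X Calibration descriptor matrix (raw scale; subset to the
#'   selected descriptors).
#' @param y Calibration response (numeric RT in minutes, or class labels).
#' @param config An [svm_config()].
#' @param X_test,y_test Optional held-out test partition.
#' @return A `qsar_model` bundle: selected descriptor names, scaling
#'   parameters, fitted linear weights and intercept, chosen
#'   hyperparameters, the CV grid table and a `metrics` list.
#' @export
svm_train_grid <- function(X, y, config = svm_config(),
                           X_test = NULL, y_test = NULL) {
  X <- as.matrix(X)
  if (!ncol(X)) stop("no descriptors selected")
  if (config$mode == "epsilon_regression" && stats::sd(y) == 0) {
    stop("DegenerateResponse: constant response")
  }
  sc <- autoscale(X)
  Xs <- sc$values
  folds <- .make_folds(nrow(X), config$cv_folds, config$cv_repeats,
                       config$seed)
  eps_grid <- if (config$mode == "epsilon_regression") config$epsilon_grid
              else NA_real_
  grid <- expand.grid(epsilon = eps_grid, cost = config$cost_grid,
                      KEEP.OUT.ATTRS = FALSE)[, 2:1]
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res[[i]] <- .cv_eval(Xs, y, config, grid$cost[i], grid$epsilon[i], folds)
  }
  if (config$mode == "epsilon_regression") {
    grid$cv_rmse <- vapply(res, `[[`, 0, "rmse")
    grid$cv_r2 <- vapply(res, `[[`, 0, "r2")
    best <- order(grid$cv_rmse, grid$cost, grid$epsilon)[1]
  } else {
    grid$cv_mcc <- vapply(res, `[[`, 0, "mcc")
    best <- order(-grid$cv_mcc, grid$cost)[1]
  }
  cost <- grid$cost[best]; epsilon <- grid$epsilon[best]
  fit <- .fit_svm(Xs, y, config, cost, epsilon)

  if (inherits(fit, "fq_linear_svr")) {
    w <- stats::setNames(fit$weights, colnames(X))
    b <- fit$intercept
  } else if (inherits(fit, "fq_const_model")) {
    w <- stats::setNames(rep(0, ncol(X)), colnames(X))
    b <- NA_real_
  } else {
    w <- drop(crossprod(fit$coefs, fit$SV))   # linear kernel weights
    b <- -fit$rho
  }
  cal_pred <- stats::predict(fit, Xs)
  metrics <- list()
  if (config$mode == "epsilon_regression") {
    mc <- qsar_metrics(y, cal_pred, "regression")
    metrics$rmse_cal <- mc$rmse; metrics$r2_cal <- mc$r2
    metrics$rmse_cv <- grid$cv_rmse[best]; metrics$r2_cv <- grid$cv_r2[best]
  } else {
    mc <- qsar_metrics(y, as.character(cal_pred), "classification")
    metrics$mcc_cal <- mc$mcc
    metrics$mcc_cv <- grid$cv_mcc[best]
  }
  test_pred <- NULL
  if (!is.null(X_test)) {
    Xts <- autoscale(as.matrix(X_test), sc)$values
    test_pred <- stats::predict(fit, Xts)
    if (config$mode == "epsilon_regression") {
      mt <- qsar_metrics(y_test, test_pred, "regression")
      metrics$rmse_test <- mt$rmse; metrics$r2_test <- mt$r2
    } else {
      mt <- qsar_metrics(y_test, as.character(test_pred), "classification")
      metrics$mcc_test <- mt$mcc
      metrics$sensitivity <- mt$sensitivity
      metrics$specificity <- mt$specificity
    }
  }
  structure(list(mode = config$mode, selected = colnames(X),
                 scaling = list(center = sc$center, scale = sc$scale),
                 fit = fit, weights = w, intercept = b,
                 cost = cost, epsilon = epsilon, grid = grid,
                 metrics = metrics, config = config,
                 calibration_pred = cal_pred, test_pred = test_pred),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("<qsar_model> %s on %d descriptors; C = %g%s\n", x$mode,
              length(x$selected), x$cost,
              if (x$mode == "epsilon_regression")
                sprintf(", epsilon = %g", x$epsilon) else ""))
  for (m in names(x$metrics)) {
    v <- x$metrics[[m]]
    if (length(v) == 1 && is.numeric(v)) cat(sprintf("  %s = %.4g\n", m, v))
  }
  invisible(x)
}

#' @export
predict.qsar_model <- function(object, newdata, ...) {
  Xs <- autoscale(as.matrix(newdata)[, object$selected, drop = FALSE],
                  object$scaling)$values
  stats::predict(object$fit, Xs)
}

#' Regression and classification performance metrics
#'
#' Regression: RMSE and the coefficient of determination
#' `R2 = 1 - SS_res / SS_tot`, which is negative whenever the prediction
#' error variance exceeds the response variance (no clamping).
#' Classification: the generalised (Gorodkin) multiclass Matthews
#' correlation coefficient plus per-class sensitivity `TP/(TP+FN)` and
#' specificity `TN/(TN+FP)`.
#'
#' @param y_true,y_pred Observed and predicted values (equal length).
#' @param mode `"regression"` or `"classification"`.
#' @return Named list: `rmse`, `r2` or `mcc`, `sensitivity`, `specificity`.
#' @export
qsar_metrics <- function(y_true, y_pred,
                         mode = c("regression", "classification")) {
  mode <- match.arg(mode)
  if (!length(y_true) || length(y_true) != length(y_pred)) {
    stop("EmptyInput: need equal-length non-empty inputs")
  }
  if (mode == "regression") {
    y_true <- as.numeric(y_true); y_pred <- as.numeric(y_pred)
    ss_res <- sum((y_true - y_pred)^2)
    ss_tot <- sum((y_true - mean(y_true))^2)
    list(rmse = sqrt(mean((y_true - y_pred)^2)),
         r2 = 1 - ss_res / ss_tot)
  } else {
    lv <- sort(unique(c(as.character(y_true), as.character(y_pred))))
    cm <- table(factor(as.character(y_true), lv),
                factor(as.character(y_pred), lv))
    s <- sum(cm); cc <- sum(diag(cm))
    tk <- rowSums(cm); pk <- colSums(cm)
    den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
    mcc <- if (den == 0) 0 else (cc * s - sum(pk * tk)) / den
    sens <- diag(cm) / tk
    spec <- vapply(seq_along(lv), function(k) {
      tn <- s - tk[k] - pk[k] + cm[k, k]
      fp <- pk[k] - cm[k, k]
      if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    }, 0)
    names(spec) <- lv
    list(mcc = mcc, sensitivity = sens, specificity = spec,
         confusion = cm)
  }
}

#' Y-randomisation (response scrambling) validation
#'
#' Retrains the epsilon-SVR at the final model's hyperparameters on
#' permuted copies of the response and reports the average cross-validated
#' R2 and RMSE over the repeats. A sound model collapses to chance level
#' (CV R2 near or below zero) when its response is scrambled.
#'
#' @param X Calibration descriptor matrix (selected descriptors, raw scale).
#' @param y Calibration response.
#' @param cost,epsilon Hyperparameters of the fitted model.
#' @param config An [svm_config()] (folds / repeats reused).
#' @param n_repeats Number of scrambles (default 50).
#' @param seed RNG seed for the permutations.
#' @param scramble Set `FALSE` to run the identical procedure on the
#'   unpermuted response (control).
#' @return List with `mean_r2_cv`, `mean_rmse_cv` and the per-repeat table.
#' @export
y_randomisation <- function(X, y, cost, epsilon, config = svm_config(),
                            n_repeats = 50, seed = 1, scramble = TRUE) {
  X <- as.matrix(X)
  Xs <- autoscale(X)$values
  set.seed(seed)
  perms <- lapply(seq_len(n_repeats), function(i) {
    if (scramble) sample(seq_along(y)) else seq_along(y)
  })
  folds <- .make_folds(nrow(X), config$cv_folds, config$cv_repeats,
                       config$seed)
  rows <- lapply(seq_len(n_repeats), function(i) {
    yp <- y[perms[[i]]]
    ev <- .cv_eval(Xs, yp, config, cost, epsilon, folds)
    data.frame(repeat_id = i, rmse_cv = ev$rmse, r2_cv = ev$r2)
  })
  per <- do.call(rbind, rows)
  list(mean_r2_cv = mean(per$r2_cv), mean_rmse_cv = mean(per$rmse_cv),
       per_repeat = per)
}

#' Model learning curve
#'
#' Grows the calibration set in Kennard-Stone selection order and, at each
#' size, retrains the SVM at the already-optimised hyperparameters,
#' recording calibration, cross-validation and test RMSE. The last point
#' (full calibration set) coincides with the final model's metrics.
#'
#' @param X Full descriptor matrix (selected descriptors, raw scale) with
#'   sample row names.
#' @param y Named response vector (same ids).
#' @param split A `qsar_split` from [kennard_stone_split()].
#' @param cost,epsilon Optimised hyperparameters.
#' @param config An [svm_config()].
#' @param step Size increment between curve points.
#' @param min_size Smallest calibration subset (default 10).
#' @return data.frame with columns n, rmse_cal, rmse_cv, rmse_test.
#' @export
learning_curve <- function(X, y, split, cost, epsilon,
                           config = svm_config(), step = 5, min_size = 10) {
  X <- as.matrix(X)
  ncal <- length(split$order)
  sizes <- unique(c(seq(min(min_size, ncal), ncal, by = step), ncal))
  Xt <- X[split$test, , drop = FALSE]
  yt <- y[split$test]
  rows <- lapply(sizes, function(nsz) {
    # subset follows the Kennard-Stone selection order, but rows keep the
    # matrix's own order so the full-size point is fold-for-fold identical
    # to the final model's CV
    ids <- rownames(X)[rownames(X) %in% split$order[seq_len(nsz)]]
    Xc <- X[ids, , drop = FALSE]; yc <- y[ids]
    sc <- autoscale(Xc); Xcs <- sc$values
    folds <- .make_folds(nsz, config$cv_folds, config$cv_repeats, config$seed)
    ev <- .cv_eval(Xcs, yc, config, cost, epsilon, folds)
    fit <- .fit_svm(Xcs, yc, config, cost, epsilon)
    rc <- qsar_metrics(yc, stats::predict(fit, Xcs), "regression")$rmse
    rt <- qsar_metrics(yt, stats::predict(
      fit, autoscale(Xt, sc)$values), "regression")$rmse
    data.frame(n = as.integer(nsz), rmse_cal = rc, rmse_cv = ev$rmse,
               rmse_test = rt)
  })
  do.call(rbind, rows)
}

#' Prediction interval half-width from test residuals
#'
#' Student-t predictive interval: half-width
#' `t(1 - alpha/2, n - 1) * sd(residuals) * sqrt(1 + 1/n)`. With test-set
#' residuals in minutes this is the "+/- x min" band within which future
#' HIC retention predictions are expected at the given confidence.
#'
#' @param residuals Test residuals (observed - predicted), length >= 3.
#' @param confidence Coverage level (default 0.95).
#' @return Half-width (same units as the residuals).
#' @export
prediction_interval <- function(residuals, confidence = 0.95) {
  n <- length(residuals)
  if (n < 3) stop("TooFew: need at least 3 residuals")
  alpha <- 1 - confidence
  stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(residuals) * sqrt(1 + 1 / n)
}

#' Complete-linkage hierarchical clustering of samples
#'
#' Agglomerative clustering with the farthest-neighbour (complete linkage)
#' criterion on Euclidean distances in descriptor space; merge heights are
#' non-decreasing.
#'
#' @param table Descriptor matrix (autoscale beforehand for comparability).
#' @return List with `merge`, `height`, `order`, `labels` and the
#'   underlying `hclust` object.
#' @export
hca_complete_linkage <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 2) stop("need at least 2 samples")
  h <- stats::hclust(stats::dist(x), method = "complete")
  list(merge = h$merge, height = h$height, order = h$order,
       labels = h$labels, hclust = h)
}

#' Exploratory PCA of a descriptor table
#'
#' @param table Autoscaled descriptor matrix.
#' @param n_components Number of components to keep (default all).
#' @return List with `scores`, `loadings` (orthonormal), `explained_variance`
#'   (eigenvalues, descending) and `proportion`.
#' @export
pca_explore <- function(table, n_components = NULL) {
  x <- as.matrix(table)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  k <- if (is.null(n_components)) length(ev) else min(n_components, length(ev))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       proportion = ev[seq_len(k)] / sum(ev))
}
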