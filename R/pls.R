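# NIPALS partial least squares (single response). The readable R fit below
# is the reference implementation; the GA fitness loop calls the compiled
# kernel (cpp_pls_cv_rmse), and the two are cross-checked in the test suite.

#' Fit a PLS1 regression model (NIPALS)
#'
#' Deterministic NIPALS decomposition. With as many components as the
#' predictor rank, training predictions coincide with the ordinary
#' least-squares fit. Components whose residual variance is numerically
#' exhausted are dropped with a warning (rank deficiency).
#'
#' @param X Predictor matrix (n x p).
#' @param y Response vector.
#' @param n_components Number of latent variables requested.
#' @return A `pls_model`: weights `W`, loadings `P`, y-loadings `q`, scores
#'   `T`, centres, the per-component coefficient path, and
#'   `n_components` actually used.
#' @export
pls_fit <- function(X, y, n_components) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), n_components >= 1)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, n_components)
  Q <- numeric(n_components)
  Tm <- matrix(0, nrow(X), n_components)
  used <- 0L
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(Xc, t)) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pl)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pl; Q[a] <- qa; Tm[, a] <- t
    used <- used + 1L
  }
  if (used < n_components) {
    warning("RankDeficient: components capped at ", used)
  }
  if (used == 0L) stop("RankDeficient: no usable component (X'y is zero)")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  Q <- Q[seq_len(used)]
  Tm <- Tm[, seq_len(used), drop = FALSE]
  coef <- W %*% solve(crossprod(P, W), Q)
  structure(list(W = W, P = P, q = Q, scores = Tm, coef = drop(coef),
                 x_center = xm, y_center = ym, n_components = used,
                 descriptors = colnames(X)),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  newdata <- as.matrix(newdata)
  k <- if (is.null(n_components)) object$n_components else
    min(n_components, object$n_components)
  Wk <- object$W[, seq_len(k), drop = FALSE]
  Pk <- object$P[, seq_len(k), drop = FALSE]
  b <- Wk %*% solve(crossprod(Pk, Wk), object$q[seq_len(k)])
  drop(sweep(newdata, 2, object$x_center) %*% b) + object$y_center
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables over %d descriptors\n",
              x$n_components, nrow(x$W)))
  invisible(x)
}

#' Cross-validated PLS RMSE per component count
#'
#' Trains NIPALS-PLS on each fold complement and evaluates the held-out
#' RMSE for every latent-variable count up to `max_components` in one pass
#' (compiled kernel).
#'
#' @param X Predictor matrix; @param y response.
#' @param folds Integer fold assignment (1..k) per row.
#' @param max_components Upper bound on latent variables.
#' @return Numeric vector of CV RMSE values, one per component count.
#' @export
pls_cv_rmse <- function(X, y, folds, max_components = 10) {
  drop(cpp_pls_cv_rmse(as.matrix(X), as.numeric(y), as.integer(folds),
                       as.integer(max_components)))
}
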