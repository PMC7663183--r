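# Matrix preparation, PLS, metrics and the exploratory tools.

test_that("variance filter drops static columns and keeps the boundary", {
  X <- cbind(a = c(1, 1, 1, 1, 1),          # constant -> removed
             b = c(0, 1e-4, 0, 1e-4, 0),    # sd ~ 5.5e-5 -> removed
             c = rnorm(5),
             d = seq(0, 4e-4, by = 1e-4))   # sd ~ 1.6e-4 -> kept
  vf <- variance_filter(X, 1e-4)
  expect_setequal(colnames(vf$table), c("c", "d"))
  expect_setequal(vf$removed, c("a", "b"))
  # column with sd exactly at the threshold is kept
  x <- c(-1, 1); x <- x / sd(x) * 1e-4
  X2 <- cbind(e = c(x, 0, 0, 0) + 10, f = rnorm(5))
  X2[, "e"] <- 10 + c(rep(1e-4, 5)) * c(-1, 1, 0, 0, 0) / sd(c(-1, 1, 0, 0, 0))
  expect_true("e" %in% colnames(variance_filter(X2, sd(X2[, "e"]))$table))
  expect_error(variance_filter(matrix(1, 3, 2)), "AllRemoved")
})

test_that("Kennard-Stone matches brute-force max-min selection", {
  # spec example: 1-D {0, 1, 10}, fraction 2/3 -> calibration {0, 10}
  X <- matrix(c(0, 1, 10), dimnames = list(c("p0", "p1", "p10"), "d"))
  X <- rbind(X, p4 = 4, p6 = 6)
  sp <- kennard_stone_split(X, 2 / 5)
  expect_identical(sp$order[1:2], c("p0", "p10"))
  expect_identical(sort(sp$test), c("p1", "p4", "p6"))

  # independent greedy oracle on random <=10-point sets
  ks_oracle <- function(xs, n_cal) {
    d <- as.matrix(dist(scale(xs)))
    pair <- which(d == max(d), arr.ind = TRUE)
    pair <- pair[pair[, 1] < pair[, 2], , drop = FALSE]
    pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
    sel <- c(pair[1, 1], pair[1, 2])
    while (length(sel) < n_cal) {
      rest <- setdiff(seq_len(nrow(xs)), sel)
      mind <- vapply(rest, function(i) min(d[i, sel]), 0)
      sel <- c(sel, rest[which.max(mind)])
    }
    sort(sel)
  }
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:10, 1)
    xs <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(paste0("s", 1:n), paste0("d", 1:3)))
    sp <- kennard_stone_split(xs, 0.7)
    expect_identical(sp$calibration,
                     paste0("s", ks_oracle(xs, round(0.7 * n))))
    expect_equal(length(sp$calibration), round(0.7 * n))
  }
})

test_that("Kennard-Stone is deterministic under duplicated rows", {
  X <- matrix(c(0, 0, 5, 5, 9, 9), dimnames = list(paste0("s", 1:6), "d"))
  s1 <- kennard_stone_split(X, 0.5)
  s2 <- kennard_stone_split(X, 0.5)
  expect_identical(s1, s2)
  # the most distant pair has ties; lowest indices win
  expect_identical(s1$order[1:2], c("s1", "s5"))
})

test_that("stratified split keeps the per-class ratio and the global count", {
  set.seed(3)
  X <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(paste0("s", 1:40), paste0("d", 1:4)))
  labels <- rep(c("chimeric", "human", "humanised"), c(10, 14, 16))
  sp <- kennard_stone_split(X, 0.8, stratify_by = labels)
  expect_identical(length(sp$calibration), 32L)
  tab <- table(labels[match(sp$calibration, rownames(X))])
  expect_equal(as.numeric(tab), c(8, 11, 13), tolerance = 1)
})

test_that("V-WSP removes collinear columns and respects the threshold", {
  set.seed(7)
  n <- 30
  base <- rnorm(n)
  X <- cbind(a = base, b = base + rnorm(n, sd = 0.05),   # |r| ~ 0.999
             c = rnorm(n), d = rnorm(n), e = -base + rnorm(n, sd = 0.05))
  kept <- vwsp_reduce(X, 0.95)
  # every retained pair is below the threshold (pairwise oracle)
  cm <- abs(cor(X[, kept, drop = FALSE]))
  diag(cm) <- 0
  expect_lt(max(cm), 0.95)
  expect_lt(length(kept), 5L)
  # threshold 1 is a no-op; identical columns collapse at 0.95
  expect_setequal(vwsp_reduce(X, 1.0), colnames(X))
  X2 <- cbind(u = base, v = base, w = rnorm(n))
  expect_length(vwsp_reduce(X2, 0.95), 2L)
})

test_that("PLS at full rank equals ordinary least squares", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(100), 20, 5)
    y <- rnorm(20)
    pm <- pls_fit(X, y, 5)
    beta <- qr.solve(cbind(1, X), y)            # closed-form normal equations
    expect_equal(predict(pm, X), drop(cbind(1, X) %*% beta),
                 tolerance = 1e-8)
  }
})

test_that("PLS handles proportional responses and centering shifts", {
  set.seed(2)
  # orthogonal centred predictors: y proportional to one column is then
  # carried entirely by the first latent variable
  X <- qr.Q(qr(scale(matrix(rnorm(60), 20, 3), scale = FALSE))) * 3
  y <- 2 * X[, 2]
  pm <- pls_fit(X, y, 1)
  expect_equal(predict(pm, X), y, tolerance = 1e-8)
  # adding a constant to y shifts predictions by that constant
  pm2 <- pls_fit(X, y + 5, 1)
  expect_equal(predict(pm2, X), y + 5, tolerance = 1e-8)
  # rank-deficient input is capped with a warning
  Xr <- cbind(X, X[, 1])
  expect_warning(pls_fit(Xr, y, 4), "RankDeficient")
})

test_that("compiled CV kernel agrees with the R reference implementation", {
  set.seed(9)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- X[, 1] - 2 * X[, 4] + rnorm(30, sd = 0.3)
  fold <- rep(1:5, each = 6)
  got <- pls_cv_rmse(X, y, fold, 4)
  want <- vapply(1:4, function(k) {
    press <- 0
    for (f in 1:5) {
      tr <- fold != f
      pm <- pls_fit(X[tr, ], y[tr], k)
      press <- press + sum((y[!tr] - predict(pm, X[!tr, , drop = FALSE]))^2)
    }
    sqrt(press / 30)
  }, 0)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("regression metrics: perfect, mean and negative-R2 cases", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(qsar_metrics(y, y, "regression"),
               list(rmse = 0, r2 = 1))
  m <- qsar_metrics(y, rep(mean(y), 5), "regression")
  expect_equal(m$r2, 0)
  # predictions worse than the mean give a negative R2
  bad <- qsar_metrics(y, rev(y) * 2, "regression")
  expect_lt(bad$r2, 0)
  expect_error(qsar_metrics(numeric(0), numeric(0)), "EmptyInput")
})

test_that("MCC equals the direct confusion-matrix formula", {
  # binary case (TP, FP, TN, FN) = (4, 1, 3, 2) via explicit labels
  y_true <- c(rep("pos", 6), rep("neg", 4))
  y_pred <- c(rep("pos", 4), rep("neg", 2), "pos", rep("neg", 3))
  m <- qsar_metrics(y_true, y_pred, "classification")
  tp <- 4; fp <- 1; tn <- 3; fn <- 2
  want <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(m$mcc, want)
  expect_equal(unname(m$sensitivity["pos"]), tp / (tp + fn))
  expect_equal(unname(m$specificity["pos"]), tn / (tn + fp))

  # multiclass: generalised formula on an enumerated confusion matrix
  set.seed(11)
  y3 <- sample(c("a", "b", "c"), 60, replace = TRUE)
  p3 <- ifelse(runif(60) < 0.7, y3, sample(c("a", "b", "c"), 60, TRUE))
  m3 <- qsar_metrics(y3, p3, "classification")
  cm <- table(factor(y3, c("a", "b", "c")), factor(p3, c("a", "b", "c")))
  s <- sum(cm); cc <- sum(diag(cm)); tk <- rowSums(cm); pk <- colSums(cm)
  want3 <- (cc * s - sum(pk * tk)) /
    (sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2)))
  expect_equal(m3$mcc, want3)
  # perfect prediction -> 1
  expect_equal(qsar_metrics(y3, y3, "classification")$mcc, 1)
})

test_that("prediction interval follows the t predictive form", {
  expect_equal(prediction_interval(rep(0, 10)), 0)
  res <- c(-0.5, 0.3, 0.8, -0.2, 0.1)
  n <- length(res)
  want <- qt(0.975, n - 1) * sd(res) * sqrt(1 + 1 / n)
  expect_equal(prediction_interval(res), want)
  # width grows with residual scale
  expect_gt(prediction_interval(res * 3), prediction_interval(res))
  expect_error(prediction_interval(c(1, 2)), "TooFew")
})

test_that("complete-linkage HCA merges in farthest-neighbour order", {
  X <- matrix(c(0, 1, 10), dimnames = list(c("a", "b", "c"), "d"))
  h <- hca_complete_linkage(X)
  expect_equal(h$height, c(1, 10))              # {a,b} at 1, then c at 10
  expect_true(all(diff(h$height) >= 0))
  # duplicate points merge at height 0
  X2 <- matrix(c(3, 3, 8), dimnames = list(c("a", "b", "c"), "d"))
  expect_equal(hca_complete_linkage(X2)$height[1], 0)
})

test_that("exploratory PCA: orthonormal loadings, descending variance", {
  set.seed(13)
  X <- matrix(rnorm(12), 4, 3)
  pc <- pca_explore(X)
  expect_equal(crossprod(pc$loadings), diag(ncol(pc$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  # eigendecomposition oracle
  Xc <- scale(X, scale = FALSE)
  ev <- eigen(cov(Xc))$values
  expect_equal(pc$explained_variance, ev[seq_along(pc$explained_variance)],
               tolerance = 1e-9)
  # full-rank reconstruction
  expect_equal(pc$scores %*% t(pc$loadings), Xc, tolerance = 1e-9,
               ignore_attr = TRUE)
  # rank-1 data -> a single nonzero component
  X1 <- outer(1:5, c(1, 2, 3))
  pc1 <- pca_explore(X1)
  expect_lt(pc1$explained_variance[2] / pc1$explained_variance[1], 1e-10)
})
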