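# GA-PLS selection and SVM grid training on small, fast configurations.
# (The full-size study conditions are exercised in the acceptance tests.)

small_ga <- function(seed = 1) {
  ga_pls_config(n_runs = 3, max_generations = 25, seed = seed)
}
small_svm <- function(seed = 1, mode = "epsilon_regression") {
  svm_config(mode = mode, cv_repeats = 3, seed = seed)
}

test_that("GA-PLS recovers a planted support on easy synthetic data", {
  d <- make_regression_dataset(fixture_spec(
    n_samples = 60, n_descriptors = 20, n_informative = 3,
    noise_sd = 0.05, seed = 21))
  sel <- ga_pls_select(autoscale(d$X)$values, d$y, small_ga(3))
  expect_true(all(d$support %in% sel$selected))
  expect_identical(nrow(sel$runs), 3L)
})

test_that("GA-PLS is deterministic under a fixed seed", {
  d <- make_regression_dataset(fixture_spec(
    n_samples = 40, n_descriptors = 12, n_informative = 2, seed = 22))
  Xs <- autoscale(d$X)$values
  s1 <- ga_pls_select(Xs, d$y, small_ga(5))
  s2 <- ga_pls_select(Xs, d$y, small_ga(5))
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$runs$fitness, s2$runs$fitness)
  s3 <- ga_pls_select(Xs, d$y, small_ga(6))
  expect_identical(ncol(s3$chromosomes), ncol(s1$chromosomes))
})

test_that("a single-descriptor table is selected outright", {
  X <- matrix(rnorm(30), dimnames = list(NULL, "only"))
  sel <- ga_pls_select(X, rnorm(30), small_ga())
  expect_identical(sel$selected, "only")
})

test_that("the regression grid enumerates 90 C/epsilon permutations", {
  cfg <- svm_config()
  expect_length(cfg$cost_grid, 10L)
  expect_length(cfg$epsilon_grid, 9L)
  d <- make_regression_dataset(fixture_spec(
    n_samples = 30, n_descriptors = 4, n_informative = 2, seed = 23))
  m <- svm_train_grid(d$X, d$y, small_svm())
  expect_identical(nrow(m$grid), 90L)
})

test_that("noiseless linear data is fit essentially perfectly", {
  d <- make_regression_dataset(fixture_spec(
    n_samples = 40, n_descriptors = 5, n_informative = 3,
    noise_sd = 0, seed = 24))
  m <- svm_train_grid(d$X, d$y, small_svm())
  expect_gte(m$metrics$r2_cal, 0.999)
  # linear weights + intercept reproduce the svm predictions
  Xs <- autoscale(d$X, m$scaling)$values
  expect_equal(unname(drop(Xs %*% m$weights + m$intercept)),
               unname(predict(m, d$X)), tolerance = 1e-6)
})

test_that("the dual-CD regression solver matches LibSVM at moderate C", {
  # independent-route check: same optimisation problem, different solver
  set.seed(30)
  for (trial in 1:3) {
    X <- matrix(rnorm(50 * 6), 50, 6)
    y <- drop(X %*% rnorm(6)) + rnorm(50, sd = 0.3)
    for (C in c(0.1, 1, 10)) {
      ref <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                        cost = C, epsilon = 0.1, scale = FALSE)
      ours <- linear_svr_fit(X, y, cost = C, epsilon = 0.1)
      expect_equal(unname(predict(ref, X)), predict(ours, X),
                   tolerance = 0.02)
    }
  }
})

test_that("classification mode separates a separable two-class toy", {
  set.seed(25)
  X <- rbind(matrix(rnorm(40, mean = -2), 20, 2),
             matrix(rnorm(40, mean = 2), 20, 2))
  colnames(X) <- c("u", "v")
  y <- rep(c("lo", "hi"), each = 20)
  m <- svm_train_grid(X, y, small_svm(mode = "c_classification"))
  expect_equal(m$metrics$mcc_cal, 1)
  expect_gte(m$metrics$mcc_cv, 0.9)
})

test_that("degenerate responses are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(svm_train_grid(X, rep(1, 10), small_svm()),
               "DegenerateResponse")
})

test_that("Y-randomisation destroys the signal but the control reproduces it", {
  d <- make_regression_dataset(fixture_spec(
    n_samples = 50, n_descriptors = 6, n_informative = 3,
    noise_sd = 0.1, seed = 26))
  m <- svm_train_grid(d$X, d$y, small_svm())
  yr <- y_randomisation(d$X, d$y, m$cost, m$epsilon, small_svm(),
                        n_repeats = 5, seed = 7)
  expect_lt(yr$mean_r2_cv, 0.2)
  expect_lt(yr$mean_r2_cv, m$metrics$r2_cv)
  # forced identity permutation = unscrambled CV metrics
  ctrl <- y_randomisation(d$X, d$y, m$cost, m$epsilon, small_svm(),
                          n_repeats = 2, seed = 7, scramble = FALSE)
  expect_equal(ctrl$per_repeat$r2_cv[1], m$metrics$r2_cv, tolerance = 1e-9)
  # seeded determinism
  yr2 <- y_randomisation(d$X, d$y, m$cost, m$epsilon, small_svm(),
                         n_repeats = 5, seed = 7)
  expect_identical(yr$per_repeat, yr2$per_repeat)
})

test_that("the learning curve ends at the final model's metrics", {
  d <- make_regression_dataset(fixture_spec(
    n_samples = 40, n_descriptors = 5, n_informative = 2,
    noise_sd = 0.2, seed = 27))
  sp <- kennard_stone_split(d$X, 0.8)
  cfg <- small_svm()
  m <- svm_train_grid(d$X[sp$calibration, ], d$y[sp$calibration], cfg,
                      X_test = d$X[sp$test, ], y_test = d$y[sp$test])
  lc <- learning_curve(d$X, d$y, sp, m$cost, m$epsilon, cfg, step = 6)
  expect_true(all(diff(lc$n) > 0))
  last <- lc[nrow(lc), ]
  expect_identical(last$n, length(sp$calibration))
  expect_equal(last$rmse_cal, m$metrics$rmse_cal, tolerance = 1e-9)
  expect_equal(last$rmse_cv, m$metrics$rmse_cv, tolerance = 1e-9)
  expect_equal(last$rmse_test, m$metrics$rmse_test, tolerance = 1e-9)
})

test_that("no stage downstream of the split touches the test rows", {
  # perturbing test-row descriptor values must not change scaling-, V-WSP-
  # or GA-derived quantities computed from the calibration partition
  d <- make_regression_dataset(fixture_spec(
    n_samples = 40, n_descriptors = 10, n_informative = 2, seed = 28))
  vf <- variance_filter(d$X)
  sp <- kennard_stone_split(vf$table, 0.8)
  Xcal <- vf$table[sp$calibration, ]
  sc1 <- autoscale(Xcal)
  kept1 <- vwsp_reduce(sc1$values, 0.95)
  sel1 <- ga_pls_select(sc1$values[, kept1], d$y[sp$calibration], small_ga(9))

  X2 <- vf$table
  X2[sp$test, ] <- X2[sp$test, ] + 100          # corrupt the held-out rows
  Xcal2 <- X2[sp$calibration, ]
  sc2 <- autoscale(Xcal2)
  kept2 <- vwsp_reduce(sc2$values, 0.95)
  sel2 <- ga_pls_select(sc2$values[, kept2], d$y[sp$calibration], small_ga(9))
  expect_identical(sc1$center, sc2$center)
  expect_identical(kept1, kept2)
  expect_identical(sel1$selected, sel2$selected)
})
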