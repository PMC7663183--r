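# Trajectory analytics: superposition, RMSD/RMSF, essential motions, SASA
# series and the interval difference.

make_line_free_coords <- function(n = 6, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = 3), n, 3)
}

test_that("Kabsch superposition removes rigid motion exactly", {
  A <- make_line_free_coords()
  expect_equal(kabsch_superpose(A, A)$rmsd, 0, tolerance = 1e-10)
  moved <- rigid_move(A, theta = pi / 2, shift = c(10, 0, -4))
  fit <- kabsch_superpose(moved, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$transformed, A, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Kabsch RMSD agrees with an exhaustive rotation-grid oracle", {
  # 4-point toy set, rotations about z only: scan 0.5-degree steps
  set.seed(4)
  A <- cbind(rnorm(4), rnorm(4), 0)
  B <- rigid_move(A, theta = 0.6, shift = c(1, 2, 0)) +
    matrix(rnorm(12, sd = 0.05), 4, 3)          # noisy target
  fit <- kabsch_superpose(A, B)
  grid_rmsd <- sapply(seq(0, 2 * pi, by = pi / 360), function(th) {
    Ar <- rigid_move(A, theta = th, shift = c(0, 0, 0))
    Ar <- sweep(Ar, 2, colMeans(Ar))
    Bc <- sweep(B, 2, colMeans(B))
    sqrt(mean(rowSums((Ar - Bc)^2)))
  })
  expect_lte(fit$rmsd, min(grid_rmsd) + 1e-3)
})

test_that("degenerate (collinear) selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "DegenerateSelection")
  expect_error(kabsch_superpose(line[1:2, ], line[1:2, ]),
               "DegenerateSelection")
})

test_that("constant trajectories give zero RMSD and RMSF", {
  st <- make_toy_structure("GAGAG", "helix")
  tr <- make_trajectory(st, fixture_spec(
    seed = 1, trajectory = list(n_frames = 8, dt_ps = 100, noise_sd = 0,
                                drift_start_frame = 3, drift_magnitude = 0)))
  expect_equal(rmsd_series(tr), rep(0, 8), tolerance = 1e-10)
  expect_equal(rmsf(tr), rep(0, 5), tolerance = 1e-10)
})

test_that("linear drift produces a monotone RMSD rise after the start frame", {
  st <- make_toy_structure(strrep("A", 8), "helix")
  tr <- make_trajectory(st, fixture_spec(
    seed = 2, trajectory = list(n_frames = 12, dt_ps = 500, noise_sd = 0,
                                drift_start_frame = 4, drift_magnitude = 3)),
    drift_atoms = 1:3)
  r <- rmsd_series(tr)
  expect_equal(r[1:4], rep(0, 4), tolerance = 1e-10)
  expect_true(all(diff(r[4:12]) > 0))
})

# Planted internal motions must be orthogonal to the 6 rigid-body modes
# (translations and infinitesimal rotations), otherwise the mean-structure
# superposition legitimately absorbs part of them; for planar or collinear
# bases even a sign flip is a proper rotation. So: non-planar (helix) bases
# and displacement patterns projected numerically off the rigid modes.
flat <- function(m) as.numeric(t(m))
unflat <- function(v) matrix(v, ncol = 3, byrow = TRUE)

rigid_basis <- function(base) {
  n <- nrow(base)
  X <- sweep(base, 2, colMeans(base))
  mats <- list(matrix(rep(c(1, 0, 0), n), n, 3, byrow = TRUE),
               matrix(rep(c(0, 1, 0), n), n, 3, byrow = TRUE),
               matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE),
               cbind(0, -X[, 3], X[, 2]),     # rotation about x
               cbind(X[, 3], 0, -X[, 1]),     # about y
               cbind(-X[, 2], X[, 1], 0))     # about z
  qr.Q(qr(sapply(mats, flat)))
}

internal_modes <- function(base, k, seed = 1) {
  set.seed(seed)
  Q <- rigid_basis(base)
  P <- matrix(rnorm(3 * nrow(base) * k), 3 * nrow(base), k)
  qr.Q(qr(P - Q %*% crossprod(Q, P)))
}

test_that("an internal oscillation has RMSF equal to its amplitude profile", {
  st <- make_toy_structure(strrep("G", 6), "helix")
  base <- as.matrix(st$atoms[, c("x", "y", "z")])
  p <- internal_modes(base, 1, seed = 2)[, 1]
  d <- 0.3                                     # small: linear regime
  frames <- lapply(c(-d, d, -d, d, -d, d), function(s) {
    base + s * unflat(p)
  })
  tr <- fab_trajectory(frames, times = 1:6 * 10, atoms = st$atoms)
  fl <- rmsf(tr)
  want <- d * sqrt(rowSums(unflat(p)^2))       # per-atom amplitude profile
  expect_equal(fl, want, tolerance = 0.05)
  # rigid motion of every frame leaves RMSF unchanged
  moved <- fab_trajectory(lapply(frames, rigid_move), times = 1:6 * 10,
                          atoms = st$atoms)
  expect_equal(rmsf(moved), fl, tolerance = 1e-6)
})

test_that("essential motions recover planted mode variances", {
  st <- make_toy_structure(strrep("G", 6), "helix")
  base <- as.matrix(st$atoms[, c("x", "y", "z")])
  M <- internal_modes(base, 2, seed = 3)
  set.seed(8)
  n_frames <- 500
  a1 <- rnorm(n_frames, sd = 0.6)              # two modes, 4:1 variance
  a2 <- rnorm(n_frames, sd = 0.3)
  frames <- lapply(seq_len(n_frames), function(i) {
    base + a1[i] * unflat(M[, 1]) + a2[i] * unflat(M[, 2])
  })
  tr <- fab_trajectory(frames, times = seq_len(n_frames), atoms = st$atoms)
  em <- essential_motion_magnitude(tr)
  # oracle: the empirical variances of the planted amplitudes
  v <- sort(c(mean((a1 - mean(a1))^2), mean((a2 - mean(a2))^2)),
            decreasing = TRUE)
  expect_equal(em$eigenvalues[1], v[1], tolerance = 0.05)
  expect_equal(em$eigenvalues[2], v[2], tolerance = 0.05)
  expect_equal(em$first_mode_magnitude, sqrt(em$eigenvalues[1]))
  # eigenvalue sum equals total coordinate variance (trace identity)
  al <- fabqsar:::.align_to_mean(tr$frames, NULL)
  X <- t(vapply(al$frames, function(f) as.numeric(t(f)),
                numeric(3 * nrow(base))))
  expect_equal(sum(em$eigenvalues),
               sum(apply(X, 2, function(c) mean((c - mean(c))^2))),
               tolerance = 1e-8)
})

test_that("motion confined to one internal mode yields one nonzero mode", {
  st <- make_toy_structure(strrep("G", 6), "helix")
  base <- as.matrix(st$atoms[, c("x", "y", "z")])
  p <- internal_modes(base, 1, seed = 4)[, 1]
  frames <- lapply(c(-0.5, 0.5, -0.5, 0.5), function(s) {
    base + s * unflat(p)
  })
  tr <- fab_trajectory(frames, times = 1:4, atoms = st$atoms)
  em <- essential_motion_magnitude(tr)
  expect_gt(em$eigenvalues[1], 0.2)
  expect_lt(em$eigenvalues[2] / em$eigenvalues[1], 0.05)
})

test_that("region SASA series matches the frame-wise single-structure oracle", {
  fab <- fixture_fab(seed = 29)[[1]]
  ann <- annotate_fab(fab$heavy, fab$light)
  st <- make_fab_structure(fab, geometry = "sphere_cluster")
  tr <- make_trajectory(st, fixture_spec(
    seed = 3, trajectory = list(n_frames = 4, dt_ps = 1000, noise_sd = 0.1,
                                drift_start_frame = 2, drift_magnitude = 0)))
  ser <- region_sasa_series(tr, ann, "CDR-H3", n_sphere_points = 240)
  expect_identical(nrow(ser), 4L)
  expect_true(all(ser$value >= 0))
  rg <- ann[ann$region == "CDR-H3", ]
  for (i in c(1, 3)) {
    surf <- residue_rsa(trajectory_frame(tr, i), n_sphere_points = 240)
    expect_equal(ser$value[i], region_sasa(surf, rg, "all"))
  }
})

test_that("the interval difference is the absolute mean step", {
  ser <- structure(data.frame(time = seq(0, 9000, by = 1000),
                              value = c(rep(100, 5), rep(150, 5))),
                   class = c("sasa_series", "data.frame"))
  expect_equal(sasa_interval_diff(ser, 5000), 50)
  ser$value <- rep(7, 10)
  expect_equal(sasa_interval_diff(ser, 5000), 0)
  # two-pass mean oracle on random values
  set.seed(5)
  ser$value <- runif(10, 50, 150)
  expect_equal(sasa_interval_diff(ser, 5000),
               abs(mean(ser$value[1:5]) - mean(ser$value[6:10])))
  expect_error(sasa_interval_diff(ser, -1), "EmptyInterval")
})

test_that("trajectory round-trips through multi-MODEL PDB", {
  st <- make_toy_structure("GAG", "extended")
  tr <- make_trajectory(st, fixture_spec(
    seed = 6, trajectory = list(n_frames = 3, dt_ps = 40, noise_sd = 0.2,
                                drift_start_frame = 2, drift_magnitude = 0)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(tr, path)
  back <- read_trajectory(path, dt_ps = 40)
  expect_length(back$frames, 3L)
  for (i in 1:3) {
    expect_equal(back$frames[[i]], tr$frames[[i]], tolerance = 1e-3,
                 ignore_attr = TRUE)
  }
})
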