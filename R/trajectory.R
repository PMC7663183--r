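# Multi-frame trajectory analytics: Kabsch superposition, RMSD series,
# per-atom RMSF about the mean structure, essential-motion magnitude from
# the coordinate-covariance eigenspectrum, per-region SASA time series and
# the before/after-split SASA interval difference. Covariances are
# unweighted (no mass weighting).

#' Construct a trajectory
#'
#' @param frames List of atoms x 3 coordinate matrices (Angstroms), constant
#'   atom count across frames.
#' @param times Frame times in picoseconds, strictly increasing.
#' @param atoms Atom metadata data.frame as in [fab_structure()] (coordinates
#'   taken from the frames).
#' @return A `fab_trajectory` object.
#' @export
fab_trajectory <- function(frames, times, atoms) {
  stopifnot(length(frames) == length(times), length(frames) >= 1)
  n <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 0L) != n)) {
    stop("atom count must be constant across frames")
  }
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(frames = frames, times = as.numeric(times), atoms = atoms),
            class = "fab_trajectory")
}

#' @export
print.fab_trajectory <- function(x, ...) {
  cat(sprintf("<fab_trajectory> %d frames x %d atoms, t = %g..%g ps\n",
              length(x$frames), nrow(x$frames[[1]]),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Frame i of a trajectory as a structure
#' @param traj A [fab_trajectory()].
#' @param i Frame index.
#' @return A [fab_structure()].
#' @export
trajectory_frame <- function(traj, i) {
  a <- traj$atoms
  a$x <- traj$frames[[i]][, 1]; a$y <- traj$frames[[i]][, 2]
  a$z <- traj$frames[[i]][, 3]
  fab_structure(a)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between a
#' mobile and a reference coordinate set over a selection, via SVD of the
#' cross-covariance with the usual determinant sign correction.
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param selection Integer atom indices used for the fit (default all);
#'   at least 3 non-collinear points.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (post-fit, over the selection) and `transformed` (the full
#'   mobile set after superposition).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3) stop("DegenerateSelection: need >= 3 atoms")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(A0, B0))
  if (s$d[2] < 1e-10 * max(s$d[1], 1)) {
    stop("DegenerateSelection: selection is (near-)collinear")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- sweep(sweep(A, 2, ca) %*% t(R), 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((fit - B)^2)))
  transformed <- sweep(sweep(mobile, 2, ca) %*% t(R), 2, cb, "+")
  list(rotation = R, translation = cb - as.numeric(R %*% ca),
       rmsd = rmsd, transformed = transformed)
}

#' RMSD of every frame against a reference
#'
#' Each frame is rigid-body superposed onto the reference over the selection
#' before the deviation is measured, so the series reflects internal motion
#' only.
#'
#' @param traj A [fab_trajectory()].
#' @param reference Reference coordinates (n x 3) or a frame index
#'   (default 1, the initial structure).
#' @param selection Atom indices (default all).
#' @return Numeric vector, one RMSD (Angstroms) per frame.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL) {
  if (is.numeric(reference) && length(reference) == 1L) {
    reference <- traj$frames[[reference]]
  }
  vapply(traj$frames, function(f) {
    kabsch_superpose(f, reference, selection)$rmsd
  }, 0)
}

# Iterated mean-structure alignment: superpose all frames onto their mean,
# recompute the mean, repeat.
.align_to_mean <- function(frames, selection, passes = 2L) {
  ref <- frames[[1]]
  for (k in seq_len(passes)) {
    frames <- lapply(frames, function(f) {
      kabsch_superpose(f, ref, selection)$transformed
    })
    ref <- Reduce(`+`, frames) / length(frames)
  }
  list(frames = frames, mean = ref)
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are aligned to their mean structure (two passes of iterated
#' mean-structure superposition), then
#' `rmsf_a = sqrt(mean_t |x_a(t) - mean_x_a|^2)`.
#'
#' @inheritParams rmsd_series
#' @return Per-atom RMSF vector (Angstroms), over all atoms.
#' @export
rmsf <- function(traj, selection = NULL) {
  al <- .align_to_mean(traj$frames, selection)
  dev <- lapply(al$frames, function(f) rowSums((f - al$mean)^2))
  unname(sqrt(Reduce(`+`, dev) / length(dev)))
}

#' Essential-motion magnitude via coordinate-covariance PCA
#'
#' Eigendecomposition of the 3N x 3N covariance of the superposed,
#' mean-centred coordinates (unweighted). The square root of the leading
#' eigenvalue measures the amplitude of the dominant collective motion.
#'
#' @inheritParams rmsd_series
#' @return List with `eigenvalues` (non-negative, descending, square
#'   Angstroms) and `first_mode_magnitude` (Angstroms).
#' @export
essential_motion_magnitude <- function(traj, selection = NULL) {
  al <- .align_to_mean(traj$frames, selection)
  if (is.null(selection)) selection <- seq_len(nrow(al$frames[[1]]))
  X <- t(vapply(al$frames, function(f) {
    as.numeric(t(f[selection, , drop = FALSE]))
  }, numeric(3 * length(selection))))
  Xc <- sweep(X, 2, colMeans(X))
  # Eigenvalues of the 3N x 3N covariance via the frame-space Gram matrix
  # (ranks are limited by the frame count).
  sv <- svd(Xc / sqrt(nrow(X)))$d
  ev <- sort(sv^2, decreasing = TRUE)
  ev <- pmax(ev, 0)
  list(eigenvalues = ev, first_mode_magnitude = sqrt(ev[1]))
}

#' Per-region SASA time series
#'
#' Cumulative residue SASA of one annotated region, evaluated frame by
#' frame with the single-frame SASA engine.
#'
#' @param traj A [fab_trajectory()].
#' @param annotation A `fab_annotation`.
#' @param region Region name (e.g. `"CDR-H3"`).
#' @param probe_radius,n_sphere_points SASA settings.
#' @return A `sasa_series`: data.frame with columns `time` (ps) and `value`
#'   (square Angstroms), with the region name attached.
#' @export
region_sasa_series <- function(traj, annotation, region,
                               probe_radius = 1.4, n_sphere_points = 960) {
  rg <- annotation[annotation$region == region, ]
  if (nrow(rg) != 1L) stop("unknown region: ", region)
  vals <- vapply(seq_along(traj$frames), function(i) {
    surf <- residue_rsa(trajectory_frame(traj, i), probe_radius = probe_radius,
                        n_sphere_points = n_sphere_points)
    region_sasa(surf, rg, "all")
  }, 0)
  structure(data.frame(time = traj$times, value = vals),
            region = region, class = c("sasa_series", "data.frame"))
}

#' SASA interval difference around a split time
#'
#' Absolute difference between the series mean before the split and from the
#' split onwards: `|mean(value[t < split]) - mean(value[t >= split])|`. With
#' the default 5 ns split this quantifies how much a region's solvent
#' exposure settled after initial relaxation.
#'
#' @param series A `sasa_series` (or data.frame with `time`, `value`).
#' @param split_time Split in picoseconds (default 5000).
#' @return Absolute mean difference (square Angstroms).
#' @export
sasa_interval_diff <- function(series, split_time = 5000) {
  before <- series$value[series$time < split_time]
  after <- series$value[series$time >= split_time]
  if (!length(before) || !length(after)) {
    stop("EmptyInterval: series must span the split time")
  }
  abs(mean(before) - mean(after))
}

#' Read a multi-frame trajectory
#'
#' Multi-MODEL PDB via [bio3d::read.pdb()], or a plain-text xyz format:
#' blank-line-separated frames of whitespace-delimited `x y z` rows (atom
#' metadata then supplied separately).
#'
#' @param path File path.
#' @param dt_ps Frame spacing in ps used to synthesise times (PDB MODELs
#'   carry no time stamps); default 40.
#' @param atoms Atom metadata for the xyz format (ignored for PDB).
#' @param format `"pdb"` or `"xyz"` (guessed from the extension).
#' @return A [fab_trajectory()].
#' @export
read_trajectory <- function(path, dt_ps = 40, atoms = NULL, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    base <- read_structure_pdb(path)
    frames <- lapply(seq_len(nrow(xyz)), function(i) {
      matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    })
    atoms <- base$atoms
  } else {
    txt <- readLines(path)
    blocks <- split(txt, cumsum(txt == ""))
    blocks <- lapply(blocks, function(b) b[b != ""])
    blocks <- blocks[lengths(blocks) > 0]
    frames <- lapply(blocks, function(b) {
      m <- do.call(rbind, lapply(strsplit(trimws(b), "[[:space:]]+"),
                                 as.numeric))
      if (ncol(m) != 3) stop("xyz frames must have 3 columns")
      m
    })
    if (is.null(atoms)) stop("xyz trajectories need atom metadata")
  }
  fab_trajectory(frames, times = (seq_along(frames) - 1) * dt_ps, atoms = atoms)
}

#' Write a trajectory as a multi-MODEL PDB
#' @param traj A [fab_trajectory()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    f <- traj$frames[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    el <- ifelse(a$element == "CA1", "C", a$element)  # pseudo-atoms are carbon
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a$serial, substr(a$name, 1, 4), bio3d::aa123(a$resname), a$chain,
      a$resno, f[, 1], f[, 2], f[, 3], substr(el, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
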