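# Seeded synthetic fixture generators for every input the workflow
# consumes: IMGT-valid Fab sequence pairs, toy structures, multi-frame
# trajectories with controlled drift/noise, and descriptor matrices with
# planted sparse linear signal, collinear blocks and class-structured
# confounding. Geometry and chemistry are deliberately naive; each
# generator records its ground truth so tests never hard-code derived
# numbers. Everything is reproducible from (spec, seed).

#' Fixture generation settings
#'
#' @param n_samples Number of Fabs / samples.
#' @param cdr_length_ranges Named list of `c(min, max)` CDR lengths;
#'   defaults: H1/H2/L1/L3 5-12, H3 6-20, L2 fixed at 3 (kappa).
#' @param n_descriptors,n_informative,beta,noise_sd Regression-generator
#'   shape: descriptor count, size of the true support, coefficient value(s)
#'   and residual noise sd.
#' @param collinear_pairs Number of descriptors duplicated (with small
#'   jitter) to create collinear pairs exceeding a 0.95 correlation.
#' @param confounder Optional list (`n_classes`, `strength`) adding
#'   class-structured offsets to the informative columns: systematic
#'   variation correlated with a class label but not with the response.
#' @param skewed_response Add a right-skew component to the response.
#' @param trajectory List: `n_frames`, `dt_ps`, `noise_sd` (A),
#'   `drift_start_frame`, `drift_magnitude` (A, linear ramp applied to a
#'   drifting atom subset).
#' @param seed RNG seed (mandatory; every generator call is a pure function
#'   of spec and seed).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_samples = 10,
                         cdr_length_ranges = list(
                           H1 = c(5L, 12L), H2 = c(5L, 10L), H3 = c(6L, 20L),
                           L1 = c(5L, 12L), L2 = c(3L, 3L), L3 = c(5L, 12L)),
                         n_descriptors = 50, n_informative = 5,
                         beta = 1, noise_sd = 0.1,
                         collinear_pairs = 0, confounder = NULL,
                         skewed_response = FALSE,
                         trajectory = list(n_frames = 51, dt_ps = 1000,
                                           noise_sd = 0.05,
                                           drift_start_frame = 6,
                                           drift_magnitude = 3),
                         seed = 1) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(as.list(environment()), class = "fixture_spec")
}

# Random residues avoiding the anchor letters C/W so the windowed anchor
# scans cannot be confused by loop content.
.rand_res <- function(n, exclude = c("C", "W")) {
  pool <- setdiff(AA_LETTERS, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# A gap-complete V-domain: FR1 26 residues (Cys at position 23), CDR1,
# positions 39-41 ending in Trp41, FR2 42-55, CDR2, FR3 39 residues ending
# in Cys104, CDR3, FR4 11 residues led by the J anchor (Trp for heavy,
# Phe for kappa).
.make_v_domain <- function(kind, lens) {
  fr1 <- paste0(.rand_res(22), "C", .rand_res(3))
  cdr1 <- .rand_res(lens[1])
  pre_w <- paste0(.rand_res(2), "W")
  fr2 <- .rand_res(14)
  cdr2 <- .rand_res(lens[2])
  fr3 <- paste0(.rand_res(38), "C")
  cdr3 <- .rand_res(lens[3])
  fr4 <- paste0(if (kind == "heavy") "W" else "F", .rand_res(10))
  paste0(fr1, cdr1, pre_w, fr2, cdr2, fr3, cdr3, fr4)
}

#' Generate IMGT-valid Fab sequence pairs
#'
#' Heavy and kappa light chains with correct conserved anchors, randomised
#' CDR loops within the configured length ranges and the packaged constant
#' domains appended, so [annotate_fab()] succeeds on every output.
#'
#' @param spec A [fixture_spec()].
#' @return Named list of `list(heavy=, light=)` [chain_sequence()] pairs,
#'   with the drawn CDR lengths attached as attribute `cdr_lengths`.
#' @export
make_fab_sequences <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  rg <- spec$cdr_length_ranges
  # sample.int keeps single-value ranges fixed (sample(x, 1) would treat a
  # scalar x as 1:x)
  draw <- function(r) r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
  out <- list(); lens_all <- list()
  for (i in seq_len(spec$n_samples)) {
    lh <- c(draw(rg$H1), draw(rg$H2), draw(rg$H3))
    ll <- c(draw(rg$L1), draw(rg$L2), draw(rg$L3))
    hv <- .make_v_domain("heavy", lh)
    lv <- .make_v_domain("kappa", ll)
    out[[paste0("mab", i)]] <- list(
      heavy = chain_sequence(paste0(hv, IGHG1_CH1), "heavy", nchar(hv)),
      light = chain_sequence(paste0(lv, IGKC_CL), "light", nchar(lv)))
    lens_all[[paste0("mab", i)]] <- c(H1 = lh[1], H2 = lh[2], H3 = lh[3],
                                      L1 = ll[1], L2 = ll[2], L3 = ll[3])
  }
  attr(out, "cdr_lengths") <- do.call(rbind, lens_all)
  out
}

#' Write Fab pairs to FASTA
#' @param fabs Output of [make_fab_sequences()].
#' @param path FASTA path (ids `<sample>_H` / `<sample>_L`).
#' @return The path, invisibly.
#' @export
write_fab_fasta <- function(fabs, path) {
  seqs <- unlist(lapply(names(fabs), function(s) {
    stats::setNames(c(fabs[[s]]$heavy$residues, fabs[[s]]$light$residues),
                    paste0(s, c("_H", "_L")))
  }))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Build a toy structure for a sequence
#'
#' One pseudo-atom per residue (element `CA1`, radius sized to reproduce
#' the residue's maximum ASA when isolated) arranged in a chosen geometry:
#' `extended` (a straight line at 5 A spacing), `helix` (a coarse spiral) or
#' `sphere_cluster` (points packed on a sphere surface, partially occluding
#' each other). Chemically naive but geometrically valid and deterministic.
#'
#' @param sequences Named list of per-chain amino-acid strings, e.g.
#'   `list(H = "ACD...", L = "GHI...")`, or a single string (chain `"A"`).
#' @param geometry `"extended"`, `"helix"` or `"sphere_cluster"`.
#' @param spacing Inter-residue spacing in Angstroms (default 5).
#' @return A [fab_structure()].
#' @export
make_toy_structure <- function(sequences, geometry = c("extended", "helix",
                                                       "sphere_cluster"),
                               spacing = 5) {
  geometry <- match.arg(geometry)
  if (is.character(sequences) && length(sequences) == 1L &&
      is.null(names(sequences))) {
    sequences <- list(A = sequences)
  }
  rows <- list()
  offset <- 0
  serial <- 0L
  for (ch in names(sequences)) {
    seq <- toupper(sequences[[ch]])
    .assert_canonical(seq, paste("chain", ch))
    res <- strsplit(seq, "")[[1]]
    n <- length(res)
    coords <- switch(geometry,
      extended = cbind(seq_len(n) * spacing, 0, offset),
      helix = {
        t <- seq_len(n) * 100 * pi / 180           # coarse helical twist
        cbind(4 * cos(t), 4 * sin(t), 1.5 * seq_len(n) + offset)
      },
      sphere_cluster = {
        pts <- .fibonacci_sphere(n) * spacing * sqrt(n) / 2
        sweep(pts, 2, c(0, 0, offset), "+")
      })
    rows[[ch]] <- data.frame(
      serial = serial + seq_len(n), name = "CA", element = "CA1",
      resname = res, resno = seq_len(n), chain = ch,
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      stringsAsFactors = FALSE)
    offset <- offset + 25 + spacing * n
    serial <- serial + n
  }
  fab_structure(do.call(rbind, rows))
}

#' Structure for an annotated Fab
#'
#' Convenience wrapper building one toy structure whose chains and residue
#' numbering line up with a `fab_annotation`.
#' @param fab A `list(heavy=, light=)` pair as from [make_fab_sequences()].
#' @param geometry,spacing Passed to [make_toy_structure()].
#' @return A [fab_structure()] with chains `H` and `L`.
#' @export
make_fab_structure <- function(fab, geometry = "sphere_cluster", spacing = 5) {
  make_toy_structure(list(H = fab$heavy$residues, L = fab$light$residues),
                     geometry, spacing)
}

#' Generate a synthetic trajectory
#'
#' Frames are the base structure plus i.i.d. Gaussian coordinate noise;
#' optionally a labelled atom subset drifts linearly (in +z) from
#' `drift_start_frame` to the final frame, reaching `drift_magnitude`
#' Angstroms — emulating the gradual domain shifts seen in a minority of
#' Fab simulations.
#'
#' @param structure A [fab_structure()] providing the base coordinates.
#' @param spec A [fixture_spec()] (`spec$trajectory` is used).
#' @param drift_atoms Integer atom indices that drift (default none).
#' @return A [fab_trajectory()] with attribute `drift` recording the
#'   programmed drift (atoms, start frame, magnitude).
#' @export
make_trajectory <- function(structure, spec = fixture_spec(),
                            drift_atoms = integer(0)) {
  set.seed(spec$seed)
  tr <- spec$trajectory
  base <- as.matrix(structure$atoms[, c("x", "y", "z")])
  n <- nrow(base)
  frames <- lapply(seq_len(tr$n_frames), function(i) {
    f <- base + matrix(stats::rnorm(3 * n, sd = tr$noise_sd), n, 3)
    if (length(drift_atoms) && i >= tr$drift_start_frame) {
      ramp <- (i - tr$drift_start_frame) /
        max(tr$n_frames - tr$drift_start_frame, 1)
      f[drift_atoms, 3] <- f[drift_atoms, 3] + ramp * tr$drift_magnitude
    }
    f
  })
  out <- fab_trajectory(frames, times = (seq_len(tr$n_frames) - 1) * tr$dt_ps,
                        atoms = structure$atoms)
  attr(out, "drift") <- list(atoms = drift_atoms,
                             start_frame = tr$drift_start_frame,
                             magnitude = tr$drift_magnitude)
  out
}

#' Generate a regression dataset with planted structure
#'
#' Standard-normal descriptors with a sparse linear signal
#' `y = X[, support] beta + noise`, optional collinear descriptor pairs
#' (|r| > 0.95 by construction), an optional class-structured confounder
#' (per-class offsets added to the informative columns after the response
#' is formed — systematic variation correlated with the class but not the
#' response), and an optional right-skew in the response. Ground truth
#' (support, beta, classes) is returned alongside.
#'
#' @param spec A [fixture_spec()].
#' @return List with `X` (matrix, samples x descriptors), `y` (named),
#'   `support` (true descriptor names), `beta`, `classes` (or NULL) and
#'   `spec`.
#' @export
make_regression_dataset <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_descriptors
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("d", seq_len(p))))
  support <- seq_len(spec$n_informative)
  beta <- rep_len(spec$beta, spec$n_informative)
  y <- drop(X[, support, drop = FALSE] %*% beta) +
    stats::rnorm(n, sd = spec$noise_sd)
  if (isTRUE(spec$skewed_response)) {
    y <- y + stats::rexp(n, rate = 0.5)    # right-skewed tail, as in real RT data
  }
  if (spec$collinear_pairs > 0) {
    k <- min(spec$collinear_pairs, p - spec$n_informative)
    src <- spec$n_informative + seq_len(k)
    dup <- p - k + seq_len(k)
    # r = 1/sqrt(1 + 0.04) ~ 0.98 > 0.95 in expectation
    X[, dup] <- X[, src] + matrix(stats::rnorm(n * k, sd = 0.2), n, k)
  }
  classes <- NULL
  if (!is.null(spec$confounder)) {
    cf <- spec$confounder
    n_cls <- cf$n_classes %||% 3L
    strength <- cf$strength %||% 1.5
    classes <- stats::setNames(
      sample(paste0("class", seq_len(n_cls)), n, replace = TRUE), rownames(X))
    # deterministic class offset pattern over the informative columns
    pat <- outer(seq_len(n_cls), support, function(k, j) {
      strength * ((k - (n_cls + 1) / 2)) * (-1)^j
    })
    X[, support] <- X[, support] +
      pat[match(classes, paste0("class", seq_len(n_cls))), , drop = FALSE]
  }
  names(y) <- rownames(X)
  list(X = X, y = y, support = colnames(X)[support], beta = beta,
       classes = classes, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
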