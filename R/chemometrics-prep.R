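# Descriptor-matrix preparation: variance filtering, autoscaling,
# Kennard-Stone (CADEX) calibration/test splitting and V-WSP collinearity
# reduction. Everything that learns parameters (scaling, retained columns)
# learns them from the calibration rows only; the split itself necessarily
# sees all samples, as the max-min design criterion requires.

#' Column-wise autoscaling
#'
#' Centres and scales a matrix to zero mean / unit standard deviation per
#' column. Pass a previously returned `scaling` to apply calibration-derived
#' parameters to new data (the only leak-free way to scale a test set).
#' Columns with zero spread scale by 1 to stay finite.
#'
#' @param x Numeric matrix.
#' @param scaling Optional list with `center` and `scale` vectors.
#' @return List with `values` (scaled matrix), `center`, `scale`.
#' @export
autoscale <- function(x, scaling = NULL) {
  x <- as.matrix(x)
  if (is.null(scaling)) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    scaling <- list(center = center, scale = scl)
  }
  ctr <- scaling$center
  scl <- scaling$scale
  if (!is.null(colnames(x)) && !is.null(names(ctr))) {
    ctr <- ctr[colnames(x)]
    scl <- scl[colnames(x)]
  }
  v <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  list(values = v, center = scaling$center, scale = scaling$scale)
}

#' Remove near-static descriptors
#'
#' Drops every column whose standard deviation is below the threshold
#' (columns exactly at the threshold are kept).
#'
#' @param table Descriptor matrix (samples x descriptors).
#' @param sd_threshold Minimum standard deviation (default 1e-4).
#' @return List with `table` (surviving columns) and `removed` (names).
#' @export
variance_filter <- function(table, sd_threshold = 1e-4) {
  x <- as.matrix(table)
  if (nrow(x) < 2) stop("variance filtering needs at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  keep <- sds >= sd_threshold
  if (!any(keep)) stop("AllRemoved: every descriptor is below the threshold")
  out <- x[, keep, drop = FALSE]
  attrs <- attributes(table)
  if (!is.null(attrs$provenance)) attr(out, "provenance") <- attrs$provenance
  list(table = out, removed = colnames(x)[!keep])
}

#' Kennard-Stone (CADEX) calibration/test split
#'
#' Deterministic max-min design: autoscale the descriptors, seed the
#' calibration set with the two most distant samples (Euclidean), then
#' repeatedly add the sample whose minimum distance to the already-selected
#' set is largest, until the calibration fraction is reached. Ties break to
#' the lowest row index. With `stratify_by`, the procedure runs per label
#' group so every class keeps (approximately) the same calibration/test
#' ratio; group sizes are rounded by largest remainder so the overall
#' calibration size is `round(fraction * n)`.
#'
#' @param table Descriptor matrix with sample row names.
#' @param calibration_fraction Fraction of samples for calibration (0.8).
#' @param stratify_by Optional per-sample labels (character/factor).
#' @return A `qsar_split`: list with `calibration`, `test` (sample ids) and
#'   `order` (calibration ids in selection order).
#' @export
kennard_stone_split <- function(table, calibration_fraction = 0.8,
                                stratify_by = NULL) {
  x <- as.matrix(table)
  n <- nrow(x)
  if (n < 5) stop("TooFewSamples: Kennard-Stone needs at least 5 samples")
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(n))
  ids <- rownames(x)
  xs <- autoscale(x)$values
  n_cal_total <- round(calibration_fraction * n)

  ks_order <- function(d2, n_cal) {
    m <- nrow(d2)
    # most distant pair; ties -> lexicographically smallest index pair
    best <- which(d2 == max(d2), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    sel <- c(best[1, 1], best[1, 2])
    while (length(sel) < n_cal) {
      rest <- setdiff(seq_len(m), sel)
      mind <- apply(d2[rest, sel, drop = FALSE], 1, min)
      sel <- c(sel, rest[which.max(mind)])   # which.max takes the first tie
    }
    sel
  }

  if (is.null(stratify_by)) {
    d2 <- as.matrix(stats::dist(xs))^2
    sel <- ks_order(d2, n_cal_total)
    order_ids <- ids[sel]
  } else {
    stratify_by <- as.character(stratify_by)
    stopifnot(length(stratify_by) == n)
    groups <- unique(stratify_by)
    sizes <- vapply(groups, function(g) sum(stratify_by == g), 0L)
    if (any(sizes == 0)) stop("EmptyStratum")
    raw <- calibration_fraction * sizes
    n_cal <- floor(raw)
    short <- n_cal_total - sum(n_cal)
    if (short > 0) {
      extra <- order(-(raw - floor(raw)), seq_along(groups))[seq_len(short)]
      n_cal[extra] <- n_cal[extra] + 1L
    } else if (short < 0) {
      give <- order(raw - floor(raw), seq_along(groups))[seq_len(-short)]
      n_cal[give] <- n_cal[give] - 1L
    }
    order_ids <- character(0)
    for (gi in seq_along(groups)) {
      rows <- which(stratify_by == groups[gi])
      if (n_cal[gi] < 2 && length(rows) >= 2 && n_cal[gi] > 0) n_cal[gi] <- 2L
      if (n_cal[gi] == 0) next
      if (length(rows) < 2) stop("EmptyStratum: stratum too small to split")
      d2 <- as.matrix(stats::dist(xs[rows, , drop = FALSE]))^2
      sel <- ks_order(d2, min(n_cal[gi], length(rows)))
      order_ids <- c(order_ids, ids[rows[sel]])
    }
  }
  structure(list(calibration = ids[sort(match(order_ids, ids))],
                 test = setdiff(ids, order_ids),
                 order = order_ids),
            class = "qsar_split")
}

#' @export
print.qsar_split <- function(x, ...) {
  cat(sprintf("<qsar_split> %d calibration / %d test samples\n",
              length(x$calibration), length(x$test)))
  invisible(x)
}

#' V-WSP collinearity reduction
#'
#' Greedy removal of highly collinear descriptors on the (autoscaled)
#' calibration matrix: descriptors are ranked by the absolute correlation of
#' their column with the first principal axis; walking down that ranking,
#' each retained descriptor discards every remaining descriptor whose
#' absolute Pearson correlation with it exceeds the threshold. Every pair of
#' retained descriptors therefore satisfies `|r| <= threshold`. A threshold
#' of 1 retains everything.
#'
#' @param table Calibration descriptor matrix.
#' @param correlation_threshold Maximum allowed absolute pairwise
#'   correlation (default 0.95).
#' @return Character vector of retained descriptor names (selection order).
#' @export
vwsp_reduce <- function(table, correlation_threshold = 0.95) {
  x <- autoscale(as.matrix(table))$values
  p <- ncol(x)
  if (p <= 1) return(colnames(x))
  cmat <- abs(suppressWarnings(stats::cor(x)))
  cmat[!is.finite(cmat)] <- 0
  pc1 <- svd(x, nu = 1, nv = 0)$u[, 1]
  score <- abs(suppressWarnings(stats::cor(x, pc1)))
  score[!is.finite(score)] <- 0
  ranking <- order(-score, seq_len(p))
  pool <- ranking
  retained <- integer(0)
  while (length(pool)) {
    k <- pool[1]
    retained <- c(retained, k)
    pool <- pool[-1]
    if (correlation_threshold < 1) {
      pool <- pool[cmat[pool, k] <= correlation_threshold]
    }
  }
  colnames(x)[retained]
}
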