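# End-to-end model development on a descriptor table: variance filter ->
# Kennard-Stone split -> calibration-only autoscaling -> V-WSP reduction ->
# consensus GA-PLS selection -> SVM grid search. Nothing downstream of the
# split ever reads the test rows until final evaluation.

#' Develop a QSAR model from a descriptor table
#'
#' Runs the full model-development procedure. For regression the response
#' is the HIC retention time in minutes; for classification a class label
#' (then the split can be stratified and GA-PLS is typically skipped).
#'
#' @param X Descriptor matrix (samples x descriptors) with row names.
#' @param y Response vector named by sample (numeric, or labels for
#'   classification).
#' @param mode `"epsilon_regression"` or `"c_classification"`.
#' @param seed Master seed for all stochastic stages.
#' @param sd_threshold Variance-filter threshold (default 1e-4).
#' @param calibration_fraction Kennard-Stone calibration share (0.8).
#' @param stratify_by Optional labels for a stratified split (e.g. species).
#' @param vwsp_threshold V-WSP correlation threshold (0.95).
#' @param ga A [ga_pls_config()], or `NULL` to skip GA-PLS selection.
#' @param svm An [svm_config()]; its mode is forced to `mode`.
#' @return A `qsar_run` list: `split`, `filtered` (descriptor names after
#'   variance filter), `vwsp_kept`, `ga` (selection report or NULL),
#'   `selected`, `model` (the fitted bundle) and `seed`.
#' @export
qsar_run <- function(X, y, mode = c("epsilon_regression", "c_classification"),
                     seed = 1, sd_threshold = 1e-4,
                     calibration_fraction = 0.8, stratify_by = NULL,
                     vwsp_threshold = 0.95,
                     ga = ga_pls_config(seed = seed),
                     svm = svm_config(seed = seed)) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))
  stopifnot(!is.null(names(y)), all(rownames(X) %in% names(y)))
  y <- y[rownames(X)]
  svm$mode <- mode

  vf <- variance_filter(X, sd_threshold)
  split <- kennard_stone_split(vf$table, calibration_fraction, stratify_by)
  Xcal <- vf$table[split$calibration, , drop = FALSE]
  ycal <- y[split$calibration]
  sc <- autoscale(Xcal)

  kept <- vwsp_reduce(sc$values, vwsp_threshold)
  ga_report <- NULL
  selected <- kept
  if (!is.null(ga) && mode == "epsilon_regression") {
    ga_report <- ga_pls_select(sc$values[, kept, drop = FALSE],
                               as.numeric(ycal), ga)
    selected <- ga_report$selected
  }
  model <- svm_train_grid(Xcal[, selected, drop = FALSE],
                          if (mode == "epsilon_regression")
                            as.numeric(ycal) else as.character(ycal),
                          svm,
                          X_test = vf$table[split$test, selected, drop = FALSE],
                          y_test = if (mode == "epsilon_regression")
                            as.numeric(y[split$test]) else
                            as.character(y[split$test]))
  structure(list(split = split, filtered = colnames(vf$table),
                 removed_static = vf$removed, vwsp_kept = kept,
                 ga = ga_report, selected = selected, model = model,
                 seed = seed, mode = mode),
            class = "qsar_run")
}

#' @export
print.qsar_run <- function(x, ...) {
  cat(sprintf(paste0("<qsar_run> %s: %d descriptors -> %d after V-WSP -> ",
                     "%d selected; %d cal / %d test\n"),
              x$mode, length(x$filtered), length(x$vwsp_kept),
              length(x$selected), length(x$split$calibration),
              length(x$split$test)))
  print(x$model)
  invisible(x)
}

#' Serialise a fitted model bundle to JSON
#'
#' Writes the selected descriptors, scaling parameters, linear weights,
#' hyperparameters and metrics — everything needed to audit or re-apply the
#' linear model without the fitted object.
#'
#' @param run A `qsar_run` (or `qsar_model`).
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_model_json <- function(run, path) {
  m <- if (inherits(run, "qsar_run")) run$model else run
  payload <- list(
    mode = m$mode,
    selected = m$selected,
    scaling = list(center = as.list(m$scaling$center),
                   scale = as.list(m$scaling$scale)),
    weights = as.list(stats::setNames(as.numeric(m$weights), m$selected)),
    intercept = m$intercept,
    cost = m$cost, epsilon = m$epsilon,
    metrics = lapply(m$metrics, function(v)
      if (is.numeric(v)) as.numeric(v) else v)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
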