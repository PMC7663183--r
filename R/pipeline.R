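# Pipeline orchestration: annotate -> descriptors -> model development
# under a single config, with a reproducibility manifest of input/output
# checksums. Stages write their outputs into a run directory; re-running
# with identical config and inputs reproduces identical checksums.

#' Run the end-to-end workflow under one config
#'
#' Config is a named list (or YAML path) with elements:
#' \describe{
#'   \item{heavy_fasta, light_fasta}{FASTA input(s); alternatively
#'     `fasta` with both chains per sample.}
#'   \item{descriptors}{`"seq2d"` or a list of PDB paths per sample for a
#'     structural table; or a pre-built descriptor CSV via
#'     `descriptor_csv` + `provenance`.}
#'   \item{response_csv}{CSV with columns `sample`, `rt_minutes` and
#'     optionally `species`.}
#'   \item{mode, seed, calibration_fraction, vwsp_threshold, sd_threshold}{
#'     Model development settings (see [qsar_run()]).}
#'   \item{ga, svm}{Optional nested lists overriding [ga_pls_config()] /
#'     [svm_config()] fields.}
#'   \item{stratify}{`TRUE` to stratify the split by species.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Run directory for outputs and the manifest.
#' @return List with the `qsar_run` result, paths of stage outputs and the
#'   manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("fabqsar_run_")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  log_msg <- function(stage, ...) {
    message(sprintf("[fabqsar:%s] %s", stage, paste0(...)))
  }
  fail <- function(stage, e) {
    stop("StageFailure in '", stage, "': ", conditionMessage(e), call. = FALSE)
  }

  # --- stage: inputs ---------------------------------------------------------
  stage_files <- character(0)
  resp <- tryCatch({
    df <- utils::read.csv(config$response_csv, stringsAsFactors = FALSE)
    stopifnot("sample" %in% names(df))
    df
  }, error = function(e) fail("response", e))

  # --- stage: descriptors ----------------------------------------------------
  desc <- tryCatch({
    if (!is.null(config$descriptor_csv)) {
      read_descriptor_csv(config$descriptor_csv,
                          provenance = config$provenance %||% "Seq2D")
    } else {
      fasta <- c(config$fasta, config$heavy_fasta, config$light_fasta)
      chains <- read_chain_fasta(fasta)
      ann <- lapply(chains, function(p) annotate_fab(p$heavy, p$light))
      reg_path <- file.path(out_dir, "regions.tsv")
      write_region_table(ann, reg_path)
      stage_files <- c(stage_files, reg_path)
      log_msg("annotate", length(ann), " Fabs -> ", reg_path)
      if (identical(config$descriptors, "seq2d") ||
          is.null(config$descriptors)) {
        build_seq2d(ann)
      } else {
        structs <- lapply(config$descriptors$pdb, read_structure_pdb)
        names(structs) <- names(ann)
        build_struct_table(structs, ann,
                           provenance = config$provenance %||% "Hom3D")
      }
    }
  }, error = function(e) fail("descriptors", e))
  desc_path <- file.path(out_dir, "descriptors.csv")
  write_descriptor_csv(desc, desc_path)

  # --- stage: model development ---------------------------------------------
  run <- tryCatch({
    ids <- intersect(rownames(desc), resp$sample)
    if (!length(ids)) stop("no overlap between descriptor and response ids")
    mode <- config$mode %||% "epsilon_regression"
    y <- if (mode == "epsilon_regression") {
      stats::setNames(resp$rt_minutes[match(ids, resp$sample)], ids)
    } else {
      stats::setNames(resp$species[match(ids, resp$sample)], ids)
    }
    strat <- NULL
    if (isTRUE(config$stratify) && "species" %in% names(resp)) {
      strat <- resp$species[match(ids, resp$sample)]
    }
    ga <- do.call(ga_pls_config,
                  utils::modifyList(list(seed = seed), config$ga %||% list()))
    svm <- do.call(svm_config,
                   utils::modifyList(list(seed = seed), config$svm %||% list()))
    qsar_run(unclass(desc)[ids, , drop = FALSE], y, mode = mode, seed = seed,
             sd_threshold = config$sd_threshold %||% 1e-4,
             calibration_fraction = config$calibration_fraction %||% 0.8,
             stratify_by = strat,
             vwsp_threshold = config$vwsp_threshold %||% 0.95,
             ga = if (isFALSE(config$run_ga)) NULL else ga, svm = svm)
  }, error = function(e) fail("model", e))
  model_path <- file.path(out_dir, "model.json")
  write_model_json(run, model_path)
  log_msg("model", "selected ", length(run$selected), " descriptors; ",
          paste(names(run$model$metrics)[1], "=",
                signif(run$model$metrics[[1]], 3)))

  # --- manifest --------------------------------------------------------------
  outputs <- c(stage_files, desc_path, model_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fabqsar")),
    seed = seed,
    config_hash = unname(tools::md5sum(.write_temp_json(config))),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(run = run, out_dir = out_dir, manifest = manifest,
       descriptor_csv = desc_path, model_json = model_path)
}

.write_temp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  f
}

#' Compare models across structural representations
#'
#' Side-by-side diagnostics for completed runs on the same samples and
#' response (e.g. Seq2D vs Hom3D vs MD3D descriptor tables): calibration,
#' cross-validation and test R2 / RMSE per representation.
#'
#' @param runs Named list of `qsar_run` objects (names label the
#'   representations).
#' @return data.frame, one row per run.
#' @export
compare_representations <- function(runs) {
  stopifnot(length(runs) >= 1, !is.null(names(runs)))
  ids <- lapply(runs, function(r) sort(c(r$split$calibration, r$split$test)))
  if (length(unique(vapply(ids, paste, "", collapse = ","))) != 1L) {
    stop("SampleMismatch: runs cover different sample sets")
  }
  rows <- lapply(names(runs), function(nm) {
    m <- runs[[nm]]$model$metrics
    data.frame(representation = nm,
               n_selected = length(runs[[nm]]$selected),
               r2_cal = m$r2_cal %||% NA_real_,
               r2_cv = m$r2_cv %||% NA_real_,
               r2_test = m$r2_test %||% NA_real_,
               rmse_cal = m$rmse_cal %||% NA_real_,
               rmse_cv = m$rmse_cv %||% NA_real_,
               rmse_test = m$rmse_test %||% NA_real_)
  })
  do.call(rbind, rows)
}
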