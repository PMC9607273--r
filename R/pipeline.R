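# End-to-end orchestration: descriptors -> filter -> split -> GA -> validate
# -> applicability domain, with JSON artifacts and a run log.

#' Pipeline run configuration
#'
#' @param dataset Path to a compound table, or a compound tibble; `NULL`
#'   means the packaged PON1 dataset.
#' @param isozyme `"Q"` or `"R"`.
#' @param descriptors Descriptor names to compute ([known_descriptors()]);
#'   default: all mass-weighted 3D-MoRSE signals plus `E1v`, `H8m`, `SIC0`
#'   — the families the published models draw from.
#' @param correlation_threshold Pre-filter cutoff in (0, 1]; default 0.95.
#' @param split_period Ordered-split period; default 5 (80:20).
#' @param ga A [ga_config()]; `NULL` skips the GA and evaluates the
#'   packaged fixture model instead (`mode = "fixture"`).
#' @param lmo_fraction,lmo_iterations Leave-many-out settings.
#' @param output_dir Directory for artifacts; `NULL` for none.
#' @param seed Global seed, fanned out to per-stage seeds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dataset = NULL, isozyme = c("Q", "R"),
                       descriptors = NULL, correlation_threshold = 0.95,
                       split_period = 5L, ga = ga_config(),
                       lmo_fraction = 0.3, lmo_iterations = 1000L,
                       output_dir = NULL, seed = 1L) {
  isozyme <- match.arg(toupper(isozyme[1]), c("Q", "R"))
  if (correlation_threshold <= 0 || correlation_threshold > 1) {
    abort("`correlation_threshold` must be in (0, 1]")
  }
  if (split_period < 2) abort("`split_period` must be >= 2")
  descriptors <- descriptors %||%
    c(sprintf("Mor%02dm", 1:32), "E1v", "H8m", "SIC0")
  structure(list(
    dataset = dataset, isozyme = isozyme, descriptors = descriptors,
    correlation_threshold = correlation_threshold,
    split_period = as.integer(split_period), ga = ga,
    lmo_fraction = lmo_fraction, lmo_iterations = as.integer(lmo_iterations),
    output_dir = output_dir, seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full QSAR pipeline
#'
#' Stages, in order: load/validate the compound table; compute (or accept)
#' the descriptor matrix; drop constant and highly correlated columns;
#' ordered-response train/test split; GA-MLR subset selection on the
#' training rows (or fixture evaluation when `config$ga` is `NULL`); full
#' validation; Williams applicability-domain analysis. Each stage is logged
#' with its input/output dimensions, and when `config$output_dir` is set the
#' descriptor matrix (CSV), best model (JSON), validation report (JSON), AD
#' table (CSV + JSON) and log are written there. Re-running with the same
#' config reproduces all artifacts.
#'
#' @param config A [run_config()].
#' @param descriptor_matrix Optional precomputed descriptor tibble
#'   (`compound_id` + numeric columns) to use instead of embedding and
#'   computing descriptors (useful when conformer tools are unavailable or
#'   descriptors come from an external program).
#' @return A list of class `qsar_run`: `compounds`, `descriptors`
#'   (filtered), `split`, `ga` (or `NULL`), `model`, `validation`, `ad`,
#'   `log` (character vector), `config`.
#' @export
run_pipeline <- function(config, descriptor_matrix = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    line
  }

  tbl <- config$dataset
  if (is.null(tbl)) {
    tbl <- pon1_dataset()
  } else if (is.character(tbl)) {
    tbl <- read_compound_table(tbl)
  } else {
    tbl <- validate_compound_table(tbl, validate_structures = FALSE)
  }
  say("dataset: %d compounds, isozyme %s", nrow(tbl), config$isozyme)
  y <- log_response(tbl, config$isozyme)

  if (is.null(descriptor_matrix)) {
    descriptor_matrix <- compute_descriptor_matrix(
      tbl, config$descriptors, seed = stage_seed(config$seed, "embed"))
    say("descriptors: computed %d columns for %d compounds",
        ncol(descriptor_matrix) - 1L, nrow(descriptor_matrix))
  } else {
    say("descriptors: user-supplied, %d columns", ncol(descriptor_matrix) - 1L)
  }
  if (!identical(descriptor_matrix$compound_id, tbl$id)) {
    descriptor_matrix <- descriptor_matrix[
      match(tbl$id, descriptor_matrix$compound_id), , drop = FALSE]
    if (anyNA(descriptor_matrix$compound_id)) {
      abort("Descriptor matrix does not cover every compound")
    }
  }

  filtered <- suppressWarnings(
    drop_correlated(descriptor_matrix, config$correlation_threshold))
  say("correlation filter (|r| > %.2f): %d -> %d columns",
      config$correlation_threshold, ncol(descriptor_matrix) - 1L,
      ncol(filtered) - 1L)

  split <- ordered_split(y, config$split_period)
  say("ordered split (period %d): %d train / %d test",
      config$split_period, length(split$train), length(split$test))

  ga_res <- NULL
  if (!is.null(config$ga)) {
    cfg <- config$ga
    cfg$seed <- stage_seed(config$seed, "ga")
    ga_res <- ga_select(filtered[split$train, , drop = FALSE], y[split$train],
                        config = cfg)
    model <- ga_res$models[[1]]
    model$response_name <- response_name(config$isozyme)
    model$train_ids <- tbl$id[split$train]
    say("GA-MLR: %d subsets scored, best fitness %.4f (%s)",
        ga_res$n_evaluated, ga_res$fitness$fitness[1],
        ga_res$fitness$descriptors[1])
  } else {
    model <- pon1_model(config$isozyme)
    model$train_ids <- tbl$id[split$train]
    say("fixture evaluation: packaged %s model", config$isozyme)
  }

  validation <- validate_model(
    descriptor_matrix, y, split = split, model = model,
    lmo_fraction = config$lmo_fraction,
    lmo_iterations = config$lmo_iterations,
    seed = stage_seed(config$seed, "validation"))
  say("validation: R2tr = %.3f, Q2LOO = %.3f%s",
      validation$fitting$r2, validation$internal$q2_loo,
      if (!is.null(validation$external))
        sprintf(", R2ext = %.3f", validation$external$r2_ext) else "")

  ad <- williams(model, descriptor_matrix, y, train = split$train)
  say("applicability domain: h* = %.3f, %d structural / %d response outliers",
      attr(ad, "h_star"),
      sum(ad$category %in% c("structural_outlier", "both")),
      sum(ad$category %in% c("response_outlier", "both")))

  run <- structure(list(
    compounds = tbl, descriptors = filtered, split = split, ga = ga_res,
    model = model, validation = validation, ad = ad, log = log_lines,
    config = config
  ), class = "qsar_run")

  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' @export
print.qsar_run <- function(x, ...) {
  cat("<qsar_run>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

# Write all artifacts of a run: config.json, descriptors.csv, model.json,
# validation.json, ad.csv (+ ad.json), run.log.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  jsonlite::write_json(list(
    isozyme = cfg$isozyme, descriptors = cfg$descriptors,
    correlation_threshold = cfg$correlation_threshold,
    split_period = cfg$split_period,
    ga = if (!is.null(cfg$ga)) unclass(cfg$ga),
    lmo_fraction = cfg$lmo_fraction, lmo_iterations = cfg$lmo_iterations,
    seed = cfg$seed
  ), file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  write_descriptor_matrix(run$descriptors, file.path(dir, "descriptors.csv"))
  write_model(run$model, file.path(dir, "model.json"))
  write_validation(run$validation, file.path(dir, "validation.json"))
  write_ad(run$ad, file.path(dir, "ad.csv"))
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Evaluate a packaged fixture model on a descriptor matrix
#'
#' Applies the published four-variable model for one isozyme — without any
#' refitting — to a descriptor matrix, and reports predictions plus the full
#' validation roster against the packaged responses (or `y` if given).
#'
#' @param isozyme `"Q"` or `"R"`.
#' @param descriptor_matrix Tibble with the model's descriptor columns.
#' @param y Observed log responses; default: log responses of the packaged
#'   dataset for that isozyme (requires matching compound ids).
#' @param split `train`/`test` indices; default: the ordered split of `y`.
#' @return A list: `predictions` (tibble `compound_id`, `.pred`),
#'   `validation` (`qsar_validation`), `model`.
#' @export
evaluate_fixture <- function(isozyme = c("Q", "R"), descriptor_matrix,
                             y = NULL, split = NULL) {
  isozyme <- match.arg(toupper(isozyme[1]), c("Q", "R"))
  model <- pon1_model(isozyme)
  missing_cols <- setdiff(names(model$terms), names(descriptor_matrix))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing descriptor column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  preds <- predict(model, descriptor_matrix)
  ids <- if ("compound_id" %in% names(descriptor_matrix)) {
    descriptor_matrix$compound_id
  } else {
    as.character(seq_len(nrow(descriptor_matrix)))
  }
  validation <- NULL
  if (is.null(y)) {
    pon1 <- pon1_dataset()
    idx <- match(ids, pon1$id)
    if (!anyNA(idx)) y <- log_response(pon1, isozyme)[idx]
  }
  if (!is.null(y)) {
    split <- split %||% ordered_split(y)
    model$train_ids <- ids[split$train]
    validation <- validate_model(descriptor_matrix, y, split = split,
                                 model = model)
  }
  list(predictions = tibble(compound_id = ids, .pred = preds),
       validation = validation, model = model)
}
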