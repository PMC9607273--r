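# Leverage-based applicability-domain analysis: hat values, critical hat,
# standardized residuals, Williams classification and plot.

#' Hat values (leverages) for query compounds
#'
#' \eqn{h_q = x_q (X^T X)^{-1} x_q^T} with `X` the intercept-augmented
#' training design matrix and `x_q` the intercept-augmented query row. For
#' training rows this reproduces the diagonal of the hat matrix, whose sum
#' is `p + 1`; it measures a compound's distance from the training
#' descriptor centroid in the model's metric.
#'
#' @param x_train Training descriptor tibble or matrix (no intercept
#'   column; one is added).
#' @param x_query Rows to score; defaults to the training rows.
#' @param descriptors Optional column subset (applied to both).
#' @return Numeric vector of leverages, one per query row.
#' @export
hat_values <- function(x_train, x_query = x_train, descriptors = NULL) {
  Xt <- cbind(1, design_matrix(x_train, descriptors))
  Xq <- cbind(1, design_matrix(x_query, descriptors))
  if (ncol(Xq) != ncol(Xt)) abort("Query columns must match training columns")
  XtX <- crossprod(Xt)
  if (rcond(XtX) < 1e-14) abort("Singular X'X: training design is rank deficient")
  unname(rowSums((Xq %*% solve(XtX)) * Xq))
}

#' Critical hat value
#'
#' The conventional applicability-domain leverage cutoff
#' \eqn{h^* = 3(p + 1)/n}: three times the mean training leverage.
#'
#' @param p Number of descriptors in the model.
#' @param n Number of training compounds.
#' @return The scalar threshold.
#' @export
#' @examples
#' critical_hat(p = 4, n = 24) # 0.625
critical_hat <- function(p, n) {
  if (!is.numeric(n) || n <= 0) abort("`n` must be a positive count")
  if (!is.numeric(p) || p < 1) abort("`p` must be >= 1")
  3 * (p + 1) / n
}

#' Williams applicability-domain analysis
#'
#' Scores every compound's leverage against the training design
#' ([hat_values()]) and its standardized residual (residual divided by the
#' training residual standard error `s`), then classifies:
#' `structural_outlier` when leverage exceeds \eqn{h^* = 3(p+1)/n},
#' `response_outlier` when `|std_residual| > sd_cutoff` (3 by default),
#' `both`, or `in_domain`. Test compounds are scored with the training-set
#' \eqn{(X^TX)^{-1}} and the training residual scale, per standard
#' Williams-plot practice.
#'
#' @param model A `qsar_mlr` whose terms name columns of `x`.
#' @param x Descriptor tibble for all compounds to score.
#' @param y Observed responses for all rows of `x`.
#' @param train Integer indices of the training rows within `x`. Defaults to
#'   rows matching the model's `train_ids`, or all rows.
#' @param sd_cutoff Standardized-residual cutoff (default 3).
#' @param refit If `TRUE` (default when `model$provenance == "fitted"`),
#'   residuals use the model's own coefficients; for fixture models the
#'   coefficients are likewise applied as-is.
#' @return A tibble of class `qsar_ad`: `compound_id`, `set`
#'   (`"train"`/`"test"`), `observed`, `predicted`, `leverage`,
#'   `std_residual`, `category`; attributes `h_star`, `s`, `sd_cutoff`,
#'   `n_train`, `p`.
#' @export
williams <- function(model, x, y, train = NULL, sd_cutoff = 3, refit = FALSE) {
  stopifnot(inherits(model, "qsar_mlr"))
  nms <- names(model$terms)
  missing_cols <- setdiff(nms, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing descriptor column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(y)) abort("Missing observed response values")
  if (length(y) != nrow(x)) abort("`y` must have one value per row of `x`")
  ids <- if ("compound_id" %in% names(x)) x$compound_id
         else if ("id" %in% names(x)) x$id
         else as.character(seq_len(nrow(x)))
  if (is.null(train)) {
    train <- if (!is.null(model$train_ids)) {
      match(model$train_ids, ids)
    } else {
      seq_len(nrow(x))
    }
    if (anyNA(train)) abort("Model train_ids not resolvable against `x`")
  }
  p <- length(nms)
  n_train <- length(train)
  if (refit) {
    model <- fit_mlr(x[train, , drop = FALSE], y[train], descriptors = nms,
                     response_name = model$response_name)
  }
  yhat <- predict(model, x)
  resid <- y - yhat
  s <- sqrt(sum(resid[train]^2) / (n_train - p - 1))
  lev <- hat_values(x[train, , drop = FALSE], x, descriptors = nms)
  h_star <- critical_hat(p, n_train)
  std <- resid / s
  category <- dplyr::case_when(
    lev > h_star & abs(std) > sd_cutoff ~ "both",
    lev > h_star ~ "structural_outlier",
    abs(std) > sd_cutoff ~ "response_outlier",
    TRUE ~ "in_domain"
  )
  out <- tibble(
    compound_id = ids,
    set = ifelse(seq_len(nrow(x)) %in% train, "train", "test"),
    observed = y, predicted = yhat,
    leverage = lev, std_residual = std, category = category
  )
  attr(out, "h_star") <- h_star
  attr(out, "s") <- s
  attr(out, "sd_cutoff") <- sd_cutoff
  attr(out, "n_train") <- n_train
  attr(out, "p") <- p
  class(out) <- c("qsar_ad", class(out))
  out
}

#' Williams plot
#'
#' Standardized residuals against leverages, with the critical-hat vertical
#' cutoff and the horizontal response-outlier band.
#'
#' @param object A `qsar_ad` tibble from [williams()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qsar_ad
#' @export
autoplot.qsar_ad <- function(object, ...) {
  h_star <- attr(object, "h_star")
  cutoff <- attr(object, "sd_cutoff")
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$leverage, y = .data$std_residual,
                 colour = .data$set)) +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = h_star, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Leverage (hat value)",
                  y = "Standardized residual",
                  colour = NULL,
                  title = "Williams plot",
                  subtitle = sprintf("h* = %.3f, +/-%g s cutoff", h_star, cutoff)) +
    ggplot2::theme_minimal()
}

#' Observed-vs-predicted endpoint plot
#'
#' @param ad A `qsar_ad` tibble from [williams()].
#' @return A ggplot object.
#' @export
plot_endpoint <- function(ad) {
  ggplot2::ggplot(ad, ggplot2::aes(x = .data$observed, y = .data$predicted,
                                   colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Observed log rate", y = "Predicted log rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write an applicability-domain table and JSON summary
#'
#' @param ad A `qsar_ad`.
#' @param path Output CSV path; a `.json` sibling is written alongside.
#' @return `path`, invisibly.
#' @export
write_ad <- function(ad, path) {
  readr::write_csv(as_tibble(as.data.frame(ad)), path)
  jsonlite::write_json(list(
    h_star = attr(ad, "h_star"), s = attr(ad, "s"),
    sd_cutoff = attr(ad, "sd_cutoff"), n_train = attr(ad, "n_train"),
    p = attr(ad, "p"),
    n_structural_outliers = sum(ad$category %in% c("structural_outlier", "both")),
    n_response_outliers = sum(ad$category %in% c("response_outlier", "both"))
  ), sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(path)
}
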