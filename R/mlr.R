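# Multiple-linear-regression models over descriptor subsets, including the
# published four-variable PON1 fixture models.

#' Construct an MLR model object directly from coefficients
#'
#' @param intercept Scalar intercept.
#' @param terms Named numeric vector of descriptor coefficients (names are
#'   descriptor-column names; must be unique).
#' @param response_name Label of the modelled response.
#' @param train_ids Character vector of compound ids the model was fitted on
#'   (may be `NULL` for a fixture whose training compounds are external).
#' @param provenance `"fitted"` or `"paper-fixture"`.
#' @param fit_seed Optional integer seed recorded for fitted models.
#' @return An object of class `qsar_mlr`.
#' @export
mlr_model <- function(intercept, terms, response_name = "response",
                      train_ids = NULL, provenance = "fitted",
                      fit_seed = NA_integer_) {
  if (is.null(names(terms)) || any(names(terms) == "")) {
    abort("`terms` must be a named numeric vector")
  }
  if (anyDuplicated(names(terms))) {
    abort("Descriptor names within a model must be unique")
  }
  structure(
    list(intercept = as.numeric(intercept), terms = terms,
         response_name = response_name, train_ids = train_ids,
         provenance = provenance, fit_seed = as.integer(fit_seed),
         training = NULL),
    class = "qsar_mlr")
}

#' Fit an ordinary-least-squares MLR on chosen descriptors
#'
#' @param x A descriptor tibble (`compound_id` + numeric columns) restricted
#'   to the training compounds, or a plain numeric matrix/data frame.
#' @param y Numeric response vector, same length as rows of `x`.
#' @param descriptors Optional character vector selecting columns of `x`;
#'   default all descriptor columns.
#' @param response_name Response label stored on the model.
#' @return A `qsar_mlr` with the underlying `lm` fit retained in
#'   `$training` for diagnostics.
#' @export
fit_mlr <- function(x, y, descriptors = NULL, response_name = "response") {
  ids <- if (is.data.frame(x) && "compound_id" %in% names(x)) x$compound_id
  X <- if (is.data.frame(x)) descriptor_values(as_tibbleish(x)) else as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(descriptors)) {
    missing <- setdiff(descriptors, colnames(X))
    if (length(missing) > 0) {
      abort(paste0("Descriptor column(s) not present: ",
                   paste(missing, collapse = ", ")))
    }
    X <- X[, descriptors, drop = FALSE]
  }
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) abort("`y` must have one value per row of `x`")
  if (n < p + 2) abort("Need at least p + 2 observations to fit p descriptors")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, p + 1)] - 1L]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- lm(.y ~ ., data = df)
  cf <- coef(fit)
  model <- mlr_model(cf[1], cf[-1], response_name = response_name,
                     train_ids = ids, provenance = "fitted")
  model$training <- list(lm = fit, X = X, y = y)
  model
}

# fit_mlr accepts plain data frames too; wrap so descriptor_values works.
as_tibbleish <- function(x) {
  x <- as_tibble(x)
  if (!"compound_id" %in% names(x)) {
    x <- dplyr::bind_cols(tibble(compound_id = as.character(seq_len(nrow(x)))), x)
  }
  x
}

#' Predict from an MLR model
#'
#' \eqn{\hat y_i = b_0 + \sum_j b_j x_{ij}} over the model's descriptor
#' columns, which must all be present in `newdata`.
#'
#' @param object A `qsar_mlr`.
#' @param newdata A descriptor tibble or data frame containing every model
#'   descriptor as a column.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
#' @examples
#' q <- pon1_model("Q")
#' predict(q, data.frame(Mor10m = 0, Mor17m = 0, E1v = 0, H8m = 0)) # -0.487
predict.qsar_mlr <- function(object, newdata, ...) {
  nms <- names(object$terms)
  missing <- setdiff(nms, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("Missing descriptor column(s): ",
                 paste(missing, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(newdata)[nms])
  as.numeric(object$intercept + X %*% object$terms)
}

#' @export
print.qsar_mlr <- function(x, ...) {
  rhs <- paste(sprintf("%+.4g*%s", x$terms, names(x$terms)), collapse = " ")
  cat(sprintf("<qsar_mlr> %s = %.4g %s  [%s]\n", x$response_name,
              x$intercept, rhs, x$provenance))
  invisible(x)
}

#' @describeIn mlr_model Tidy the coefficients (term, estimate).
#' @method tidy qsar_mlr
#' @param x,object A `qsar_mlr`.
#' @param ... Unused.
#' @export
tidy.qsar_mlr <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$terms)),
         estimate = c(x$intercept, unname(x$terms)))
}

#' @describeIn mlr_model One-row model summary (terms, provenance, training
#'   fit statistics when the model was fitted in-session).
#' @method glance qsar_mlr
#' @export
glance.qsar_mlr <- function(x, ...) {
  out <- tibble(response = x$response_name, n_terms = length(x$terms),
                provenance = x$provenance,
                n_train = if (!is.null(x$training)) length(x$training$y) else NA_integer_)
  if (!is.null(x$training)) {
    fm <- fit_metrics(x$training$y, predict(x, as.data.frame(x$training$X)),
                      p = length(x$terms))
    out$r2_tr <- fm$r2
    out$rmse_tr <- fm$rmse
  }
  out
}

#' The published four-variable PON1 models as packaged fixtures
#'
#' The final models for the two isozymes, with coefficients exactly as
#' published (log10 relative hydrolysis rate, phenyl acetate = 100):
#' \describe{
#'   \item{Q}{`-0.487 + 2.066 Mor10m + 3.970 Mor17m + 3.319 E1v - 25.907 H8m`}
#'   \item{R}{`4.879 - 9.472 SIC0 + 5.054 Mor17m - 3.861 Mor22m - 2.763 Mor25m`}
#' }
#' These are fixtures: applying them to descriptor values computed by this
#' package evaluates the published coefficients on open-toolchain conformers
#' and descriptor implementations, not on the proprietary toolchain the
#' models were derived with, so the resulting statistics are qualitative
#' reference output.
#'
#' @param isozyme `"Q"` or `"R"`.
#' @return A `qsar_mlr` with provenance `"paper-fixture"`.
#' @export
#' @examples
#' pon1_model("Q")$intercept # -0.487
pon1_model <- function(isozyme = c("Q", "R")) {
  isozyme <- match.arg(toupper(isozyme[1]), c("Q", "R"))
  if (isozyme == "Q") {
    mlr_model(-0.487,
              c(Mor10m = 2.066, Mor17m = 3.970, E1v = 3.319, H8m = -25.907),
              response_name = response_name("Q"), provenance = "paper-fixture")
  } else {
    mlr_model(4.879,
              c(SIC0 = -9.472, Mor17m = 5.054, Mor22m = -3.861, Mor25m = -2.763),
              response_name = response_name("R"), provenance = "paper-fixture")
  }
}

#' Serialize / deserialize an MLR model as JSON
#'
#' @param model A `qsar_mlr`.
#' @param path JSON file path.
#' @return `write_model()`: `path`, invisibly. `read_model()`: a `qsar_mlr`.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(
    intercept = model$intercept,
    terms = as.list(model$terms),
    response_name = model$response_name,
    train_ids = model$train_ids,
    provenance = model$provenance,
    fit_seed = if (is.na(model$fit_seed)) NULL else model$fit_seed
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mlr_model(obj$intercept, unlist(obj$terms),
            response_name = obj$response_name,
            train_ids = obj$train_ids,
            provenance = obj$provenance,
            fit_seed = obj$fit_seed %||% NA_integer_)
}
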