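# Fitting, internal-validation and external-validation statistics for MLR
# QSAR models, plus y-scrambling.

#' Lin's concordance correlation coefficient
#'
#' \deqn{CCC = \frac{2\,\mathrm{cov}(y, \hat y)}{\sigma_y^2 + \sigma_{\hat y}^2
#'   + (\bar y - \bar{\hat y})^2},}
#' with population (divisor n) moments; penalizes both imprecision and
#' location/scale shift, so `|CCC| <= |r|` always.
#'
#' @param y,yhat Numeric vectors of equal length.
#' @return A scalar in \[-1, 1\].
#' @export
ccc <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("`y` and `yhat` must have equal length")
  n <- length(y)
  my <- mean(y); mp <- mean(yhat)
  vy <- mean((y - my)^2); vp <- mean((yhat - mp)^2)
  sxy <- mean((y - my) * (yhat - mp))
  2 * sxy / (vy + vp + (my - mp)^2)
}

#' Fitting statistics for observed vs predicted responses
#'
#' The standard MLR fitting roster: \eqn{R^2 = 1 - SS_{res}/SS_{tot}},
#' adjusted \eqn{R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-p-1)}, RMSE with divisor
#' `n` (the cross-validation-software convention), MAE, residual standard
#' error `s` with divisor `n - p - 1`, the overall F statistic
#' \eqn{(SS_{reg}/p)/(SS_{res}/(n-p-1))}, and Lin's concordance [ccc()].
#' RMSE and `s` intentionally use different divisors: published QSAR tables
#' list both, and the pair is only mutually consistent under this convention.
#'
#' @param y Observed responses.
#' @param yhat Predicted responses.
#' @param p Number of descriptors in the model.
#' @return A one-row tibble: `r2`, `r2_adj`, `rmse`, `mae`, `ccc`, `s`, `f`,
#'   `n`, `p`.
#' @export
#' @examples
#' fit_metrics(c(0, 1, 2), c(0, 1, 3), p = 1)$r2 # 0.5
fit_metrics <- function(y, yhat, p) {
  n <- length(y)
  if (length(yhat) != n) abort("`y` and `yhat` must have equal length")
  if (n < p + 2) abort("Need at least p + 2 observations")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) abort("Zero response variance: R^2 undefined")
  ssres <- sum((y - yhat)^2)
  r2 <- 1 - ssres / sstot
  tibble(
    r2 = r2,
    r2_adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
    rmse = sqrt(ssres / n),
    mae = mean(abs(y - yhat)),
    ccc = ccc(y, yhat),
    s = sqrt(ssres / (n - p - 1)),
    f = ((sstot - ssres) / p) / (ssres / (n - p - 1)),
    n = n, p = p
  )
}

# Internal: intercept-augmented design matrix from tibble/matrix input.
design_matrix <- function(x, descriptors = NULL) {
  X <- if (is.data.frame(x)) descriptor_values(as_tibbleish(x)) else as.matrix(x)
  if (!is.null(descriptors)) X <- X[, descriptors, drop = FALSE]
  X
}

#' Leave-one-out cross-validation by closed-form PRESS
#'
#' For OLS the deleted residual is \eqn{e_i / (1 - h_{ii})}, so
#' \eqn{PRESS = \sum_i (e_i/(1-h_{ii}))^2} without refitting, and
#' \eqn{Q^2_{LOO} = 1 - PRESS/SS_{tot}}. Identical (to rounding) to
#' explicitly refitting the model n times.
#'
#' @param x Descriptor tibble or numeric matrix (training rows).
#' @param y Training responses.
#' @param descriptors Optional column subset.
#' @return One-row tibble: `q2_loo`, `rmse_cv`, `mae_cv`, `ccc_cv`, `press`.
#' @export
q2_loo <- function(x, y, descriptors = NULL) {
  X <- design_matrix(x, descriptors)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 3) abort("Need at least p + 3 observations for LOO validation")
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) abort("Design matrix is rank deficient")
  h <- rowSums(qr.Q(qrX)^2)
  if (any(h > 1 - 1e-10)) {
    abort("Degenerate leverage (h = 1): a compound is fit exactly by the rest")
  }
  e <- qr.resid(qrX, y)
  e_del <- e / (1 - h)
  yhat_del <- y - e_del
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) abort("Zero response variance")
  tibble(
    q2_loo = 1 - sum(e_del^2) / sstot,
    rmse_cv = sqrt(mean(e_del^2)),
    mae_cv = mean(abs(e_del)),
    ccc_cv = ccc(y, yhat_del),
    press = sum(e_del^2)
  )
}

#' Leave-many-out cross-validation
#'
#' Repeatedly holds out a random `leave_fraction` of the training compounds,
#' refits on the remainder and predicts the holdout; squared prediction
#' errors and squared deviations of the holdout responses from each fit
#' set's mean are pooled across iterations, and
#' \eqn{Q^2_{LMO} = 1 - \sum PRESS_{group} / \sum SS_{group}}. As the group
#' size shrinks to one compound this approaches \eqn{Q^2_{LOO}}.
#' Deterministic given `seed`.
#'
#' @inheritParams q2_loo
#' @param leave_fraction Proportion held out per iteration, in (0, 0.5).
#' @param iterations Number of random holdouts (>= 1); default 1000.
#' @param seed Integer RNG seed.
#' @return One-row tibble: `q2_lmo`, `leave_fraction`, `iterations`.
#' @export
q2_lmo <- function(x, y, leave_fraction = 0.3, iterations = 1000, seed = 1L,
                   descriptors = NULL) {
  if (!is.numeric(leave_fraction) || leave_fraction <= 0 || leave_fraction >= 0.5) {
    abort("`leave_fraction` must be in (0, 0.5)")
  }
  if (!is.numeric(iterations) || iterations < 1) {
    abort("`iterations` must be >= 1")
  }
  X <- design_matrix(x, descriptors)
  n <- nrow(X); p <- ncol(X)
  m <- max(1L, round(leave_fraction * n))
  if (n - m < p + 2) {
    abort("Holdout group too large: refit would have fewer than p + 2 rows")
  }
  parts <- with_seed(seed, vapply(seq_len(iterations), function(i) {
    out <- sample.int(n, m)
    Xi <- cbind(1, X[-out, , drop = FALSE])
    b <- qr.coef(qr(Xi), y[-out])
    pred <- cbind(1, X[out, , drop = FALSE]) %*% b
    c(sse = sum((y[out] - pred)^2),
      sst = sum((y[out] - mean(y[-out]))^2))
  }, c(sse = 0, sst = 0)))
  tibble(q2_lmo = 1 - sum(parts["sse", ]) / sum(parts["sst", ]),
         leave_fraction = leave_fraction,
         iterations = as.integer(iterations))
}

#' y-scrambling (response randomization)
#'
#' Refits the model on randomly permuted responses to check that the real
#' fit is not attainable by chance: a sound model's \eqn{R^2} and
#' \eqn{Q^2_{LOO}} should sit far above the scrambled distributions.
#'
#' @inheritParams q2_loo
#' @param iterations Number of permutations (>= 10); default 100.
#' @param seed Integer RNG seed.
#' @return A list of class `qsar_scramble`: `runs` (tibble of per-iteration
#'   `r2`/`q2`), `mean_r2`, `mean_q2`, and the unscrambled `r2`/`q2`.
#' @export
y_scramble <- function(x, y, iterations = 100, seed = 1L, descriptors = NULL) {
  if (!is.numeric(iterations) || iterations < 10) {
    abort("`iterations` must be >= 10")
  }
  X <- design_matrix(x, descriptors)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 3) abort("Need at least p + 3 observations")
  one_fit <- function(yy) {
    qrX <- qr(cbind(1, X))
    e <- qr.resid(qrX, yy)
    h <- rowSums(qr.Q(qrX)^2)
    sstot <- sum((yy - mean(yy))^2)
    c(r2 = 1 - sum(e^2) / sstot,
      q2 = 1 - sum((e / (1 - h))^2) / sstot)
  }
  base <- one_fit(y)
  runs <- with_seed(seed, t(vapply(seq_len(iterations), function(i) {
    one_fit(sample(y)) }, c(r2 = 0, q2 = 0))))
  structure(list(
    runs = as_tibble(as.data.frame(runs)),
    mean_r2 = mean(runs[, "r2"]), mean_q2 = mean(runs[, "q2"]),
    r2 = unname(base["r2"]), q2 = unname(base["q2"]),
    iterations = as.integer(iterations), seed = as.integer(seed)
  ), class = "qsar_scramble")
}

#' @export
print.qsar_scramble <- function(x, ...) {
  cat(sprintf(paste0(
    "<y-scrambling> %d permutations\n",
    "  model:     R2 = %.3f, Q2LOO = %.3f\n",
    "  scrambled: mean R2 = %.3f, mean Q2LOO = %.3f\n"),
    x$iterations, x$r2, x$q2, x$mean_r2, x$mean_q2))
  invisible(x)
}

#' Full validation report for an MLR model
#'
#' Computes the complete criterion roster published for QSAR models: fitting
#' statistics on the training set, internal validation (leave-one-out and
#' leave-many-out cross-validation with their RMSE/MAE/CCC companions), and
#' external validation on the held-out test set. External \eqn{R^2} centers
#' \eqn{SS_{tot}} on the external set's own mean by default; set
#' `external_center = "training"` for the variant centered on the training
#' mean.
#'
#' @param x Descriptor tibble covering all compounds (train + test rows).
#' @param y Observed responses for all rows of `x`.
#' @param split A list with `train`/`test` integer indices
#'   ([ordered_split()]), or `NULL` to validate on the full set with no
#'   external block.
#' @param model A fitted or fixture `qsar_mlr` to evaluate; if `NULL`, an
#'   OLS model is fitted on the training rows using `descriptors`.
#' @param descriptors Descriptor subset used when fitting (defaults to the
#'   model's terms, or all columns).
#' @param lmo_fraction,lmo_iterations,seed Leave-many-out settings.
#' @param external_center `"external"` (default) or `"training"`.
#' @return A list of class `qsar_validation` with elements `fitting`,
#'   `internal`, `external` (tibbles; `external` is `NULL` without a test
#'   set), `model`, `n_train`, `n_test`, `p`.
#' @export
validate_model <- function(x, y, split = NULL, model = NULL,
                           descriptors = NULL, lmo_fraction = 0.3,
                           lmo_iterations = 1000, seed = 1L,
                           external_center = c("external", "training")) {
  external_center <- match.arg(external_center)
  if (is.null(split)) split <- list(train = seq_along(y), test = integer(0))
  descriptors <- descriptors %||% if (!is.null(model)) names(model$terms)
  xt <- x[split$train, , drop = FALSE]
  yt <- y[split$train]
  if (is.null(model)) {
    model <- fit_mlr(xt, yt, descriptors = descriptors)
  }
  descriptors <- names(model$terms)
  p <- length(descriptors)
  yhat_tr <- predict(model, xt)
  fitting <- fit_metrics(yt, yhat_tr, p = p)
  # Internal validation always re-estimates coefficients per holdout: it
  # assesses the descriptor subset, not frozen coefficients.
  internal <- dplyr::bind_cols(
    q2_loo(xt, yt, descriptors = descriptors)[c("q2_loo", "rmse_cv", "mae_cv", "ccc_cv")],
    q2_lmo(xt, yt, leave_fraction = lmo_fraction,
           iterations = lmo_iterations, seed = seed,
           descriptors = descriptors)["q2_lmo"]
  )
  external <- NULL
  if (length(split$test) > 0) {
    xe <- x[split$test, , drop = FALSE]
    ye <- y[split$test]
    yhat_ext <- predict(model, xe)
    center <- if (external_center == "external") mean(ye) else mean(yt)
    sstot <- sum((ye - center)^2)
    ssres <- sum((ye - yhat_ext)^2)
    external <- tibble(
      r2_ext = 1 - ssres / sstot,
      rmse_ext = sqrt(mean((ye - yhat_ext)^2)),
      mae_ext = mean(abs(ye - yhat_ext)),
      ccc_ext = ccc(ye, yhat_ext)
    )
  }
  structure(list(
    fitting = fitting, internal = internal, external = external,
    model = model, n_train = length(split$train),
    n_test = length(split$test), p = p
  ), class = "qsar_validation")
}

#' @export
print.qsar_validation <- function(x, ...) {
  f <- x$fitting; i <- x$internal
  cat(sprintf("<qsar_validation> %d training / %d test compounds, p = %d\n",
              x$n_train, x$n_test, x$p))
  cat("Fitting criteria\n")
  cat(sprintf("  R2 tr = %.3f, R2adj = %.3f, RMSE = %.3f, MAE tr = %.3f,\n",
              f$r2, f$r2_adj, f$rmse, f$mae))
  cat(sprintf("  CCC tr = %.3f, s = %.3f, F = %.3f\n", f$ccc, f$s, f$f))
  cat("Internal validation criteria\n")
  cat(sprintf("  Q2LOO = %.3f, RMSE cv = %.3f, MAE cv = %.3f,\n",
              i$q2_loo, i$rmse_cv, i$mae_cv))
  cat(sprintf("  Q2LMO = %.3f, CCC cv = %.3f\n", i$q2_lmo, i$ccc_cv))
  if (!is.null(x$external)) {
    e <- x$external
    cat("External validation criteria\n")
    cat(sprintf("  R2 ext = %.3f, RMSE ext = %.3f, MAE ext = %.3f, CCC ext = %.3f\n",
                e$r2_ext, e$rmse_ext, e$mae_ext, e$ccc_ext))
  }
  invisible(x)
}

#' @describeIn validate_model All criteria as one long tibble
#'   (`block`, `metric`, `value`).
#' @param ... Unused.
#' @method tidy qsar_validation
#' @export
tidy.qsar_validation <- function(x, ...) {
  blocks <- list(fitting = x$fitting[c("r2", "r2_adj", "rmse", "mae", "ccc", "s", "f")],
                 internal = x$internal)
  if (!is.null(x$external)) blocks$external <- x$external
  purrr::imap_dfr(blocks, function(tb, nm) {
    tidyr::pivot_longer(tb, dplyr::everything(), names_to = "metric",
                        values_to = "value") |>
      dplyr::mutate(block = nm, .before = 1)
  })
}

#' @describeIn validate_model One-row summary of the headline criteria.
#' @method glance qsar_validation
#' @export
glance.qsar_validation <- function(x, ...) {
  out <- tibble(r2_tr = x$fitting$r2, r2_adj = x$fitting$r2_adj,
                rmse_tr = x$fitting$rmse, q2_loo = x$internal$q2_loo,
                q2_lmo = x$internal$q2_lmo,
                n_train = x$n_train, n_test = x$n_test, p = x$p)
  if (!is.null(x$external)) {
    out$r2_ext <- x$external$r2_ext
    out$rmse_ext <- x$external$rmse_ext
  }
  out
}

#' Serialize a validation report to JSON
#' @param report A `qsar_validation`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_validation <- function(report, path) {
  jsonlite::write_json(list(
    fitting = as.list(report$fitting),
    internal = as.list(report$internal),
    external = if (!is.null(report$external)) as.list(report$external),
    n_train = report$n_train, n_test = report$n_test, p = report$p
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
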