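test_that("hat values match the closed form and the matrix-product oracle", {
  # single centered predictor: h_i = 1/n + (x - xbar)^2 / SS_x
  x <- matrix(c(-1, 0, 1), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(hat_values(x), c(5 / 6, 1 / 3, 5 / 6), tolerance = 1e-12)
  # random instance: direct evaluation of the projection formula
  withr::with_seed(13, {
    X <- matrix(stats::rnorm(80), 20, 4)
    Q <- matrix(stats::rnorm(12), 3, 4)
  })
  colnames(X) <- colnames(Q) <- paste0("x", 1:4)
  Xi <- cbind(1, X)
  oracle <- diag(Xi %*% solve(t(Xi) %*% Xi) %*% t(Xi))
  expect_equal(hat_values(X), oracle, tolerance = 1e-10)
  Qi <- cbind(1, Q)
  oracle_q <- diag(Qi %*% solve(t(Xi) %*% Xi) %*% t(Qi))
  expect_equal(hat_values(X, Q), oracle_q, tolerance = 1e-10)
  # training leverages always sum to p + 1
  expect_equal(sum(hat_values(X)), 5, tolerance = 1e-10)
})

test_that("critical hat is exactly 3(p+1)/n", {
  expect_equal(critical_hat(4, 24), 0.625)
  expect_equal(critical_hat(1, 6), 1)
  expect_equal(critical_hat(4, 30), 0.5)
  expect_error(critical_hat(4, 0), "positive")
})

test_that("williams classifies centroid, extrapolation and response outliers", {
  sim <- generate_qsar_data(synthetic_spec(
    24, 4, informative = c(d1 = 1, d2 = -1, d3 = 0.5, d4 = 1),
    intercept = 0, noise_sd = 0.3, seed = 14))
  X <- sim$descriptors
  model <- fit_mlr(X, sim$y)
  m <- as.matrix(as.data.frame(X)[-1])

  # a query at the training centroid has (near) minimal leverage 1/n
  centroid <- as.data.frame(t(colMeans(m)))
  centroid$compound_id <- "centroid"
  far <- as.data.frame(t(apply(m, 2, max) * 10))   # far outside all ranges
  far$compound_id <- "far"
  Xq <- dplyr::bind_rows(as.data.frame(X), centroid, far)
  yq <- c(sim$y,
          predict(model, centroid),               # in-domain, zero residual
          predict(model, far) + 10 * sd(sim$y))   # fabricated response
  ad <- williams(model, tibble::as_tibble(Xq), yq, train = 1:24)
  expect_s3_class(ad, "qsar_ad")
  expect_equal(attr(ad, "h_star"), critical_hat(4, 24))
  # training block: leverages sum to p + 1, all categorized consistently
  expect_equal(sum(ad$leverage[1:24]), 5, tolerance = 1e-10)
  cen <- ad[ad$compound_id == "centroid", ]
  expect_equal(cen$leverage, 1 / 24, tolerance = 1e-10)
  expect_equal(cen$category, "in_domain")
  # the far query: leverage beyond h*, verified against the direct oracle
  farrow <- ad[ad$compound_id == "far", ]
  expect_gt(farrow$leverage, attr(ad, "h_star"))
  Xi <- cbind(1, m)
  lev_oracle <- as.numeric(
    cbind(1, as.matrix(far[colnames(m)])) %*%
      solve(t(Xi) %*% Xi) %*% t(cbind(1, as.matrix(far[colnames(m)]))))
  expect_equal(farrow$leverage, lev_oracle, tolerance = 1e-10)
  expect_true(farrow$category %in% c("structural_outlier", "both"))
  # the fabricated response trips the +/- 3 s rule
  expect_gt(abs(farrow$std_residual), 3)
  # category consistency with the two thresholds, everywhere
  expect_equal(
    ad$category,
    dplyr::case_when(
      ad$leverage > attr(ad, "h_star") & abs(ad$std_residual) > 3 ~ "both",
      ad$leverage > attr(ad, "h_star") ~ "structural_outlier",
      abs(ad$std_residual) > 3 ~ "response_outlier",
      TRUE ~ "in_domain"))
})

test_that("leverage is invariant to affine rescaling of descriptor columns", {
  sim <- generate_qsar_data(synthetic_spec(
    20, 3, informative = c(d1 = 1, d2 = 1, d3 = 1), noise_sd = 0.2, seed = 3))
  m <- as.matrix(as.data.frame(sim$descriptors)[-1])
  scaled <- sweep(sweep(m, 2, c(2, -0.5, 10), `*`), 2, c(1, -3, 0.2), `+`)
  colnames(scaled) <- colnames(m)
  expect_equal(hat_values(scaled), hat_values(m), tolerance = 1e-9)
})

test_that("williams demands observed responses and model columns", {
  sim <- generate_qsar_data(synthetic_spec(
    20, 4, informative = c(d1 = 1, d2 = 1), noise_sd = 0.2, seed = 5))
  model <- fit_mlr(sim$descriptors, sim$y, descriptors = c("d1", "d2"))
  expect_error(williams(model, sim$descriptors, c(sim$y[-1], NA)), "Missing observed")
  expect_error(williams(model, sim$descriptors[c("compound_id", "d1")], sim$y),
               "d2")
})

test_that("AD artifacts and plots are produced", {
  sim <- generate_qsar_data(synthetic_spec(
    20, 4, informative = c(d1 = 1, d2 = 1, d3 = 1, d4 = 1),
    noise_sd = 0.3, seed = 6))
  model <- fit_mlr(sim$descriptors, sim$y)
  ad <- williams(model, sim$descriptors, sim$y, train = 1:20)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ad(ad, path)
  expect_true(file.exists(path))
  js <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_equal(js$h_star, attr(ad, "h_star"), tolerance = 1e-12)
  p <- ggplot2::autoplot(ad)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_endpoint(ad), "ggplot")
})
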