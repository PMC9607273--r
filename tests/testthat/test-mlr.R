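test_that("OLS fit recovers exact linear data and matches normal equations", {
  withr::with_seed(3, {
    X <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
    beta <- c(2, -1, 0.5)
    y0 <- 1.5 + X %*% beta
    noise <- stats::rnorm(20, sd = 0.4)
  })
  # noiseless: exact recovery
  m0 <- fit_mlr(X, as.numeric(y0))
  expect_equal(m0$intercept, 1.5, tolerance = 1e-10)
  expect_equal(unname(m0$terms), beta, tolerance = 1e-10)
  # noisy: identical to the independent normal-equations solve
  y <- as.numeric(y0 + noise)
  m1 <- fit_mlr(X, y)
  Xi <- cbind(1, X)
  b_ne <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  expect_equal(c(m1$intercept, unname(m1$terms)), as.numeric(b_ne),
               tolerance = 1e-8)
  # residual orthogonality to columns and constant
  r <- y - predict(m1, as.data.frame(X))
  expect_equal(sum(r), 0, tolerance = 1e-9)
  expect_equal(as.numeric(t(X) %*% r), rep(0, 3), tolerance = 1e-8)
})

test_that("rank-deficient designs are refused with the collinear column named", {
  X <- cbind(a = rep(1, 10) * 0, b = stats::rnorm(10))
  expect_error(fit_mlr(X, stats::rnorm(10)), "rank deficient")
  X2 <- matrix(stats::rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  X3 <- cbind(X2, a_copy = X2[, "a"])
  expect_error(fit_mlr(X3, stats::rnorm(10)), "a_copy")
})

test_that("packaged fixture models carry the published equations", {
  q <- pon1_model("Q")
  r <- pon1_model("R")
  expect_length(q$terms, 4)
  expect_length(r$terms, 4)
  expect_named(q$terms, c("Mor10m", "Mor17m", "E1v", "H8m"))
  expect_named(r$terms, c("SIC0", "Mor17m", "Mor22m", "Mor25m"))
  zero_q <- data.frame(Mor10m = 0, Mor17m = 0, E1v = 0, H8m = 0)
  zero_r <- data.frame(SIC0 = 0, Mor17m = 0, Mor22m = 0, Mor25m = 0)
  expect_equal(predict(q, zero_q), -0.487)
  expect_equal(predict(r, zero_r), 4.879)
  # unit Mor17m row: intercept + its coefficient
  one <- data.frame(Mor10m = 0, Mor17m = 1, E1v = 0, H8m = 0)
  expect_equal(predict(q, one), -0.487 + 3.970, tolerance = 1e-12)
  expect_error(predict(q, zero_r), "Mor10m")
})

test_that("models serialize to JSON and back without loss", {
  m <- fit_mlr(matrix(stats::rnorm(40), 20, 2,
                      dimnames = list(NULL, c("x1", "x2"))),
               stats::rnorm(20), response_name = "log_rate_q")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$terms, m$terms)
  expect_equal(back$response_name, "log_rate_q")
  # fixture round-trip preserves provenance
  write_model(pon1_model("R"), path)
  expect_equal(read_model(path)$provenance, "paper-fixture")
})

test_that("tidy and glance expose coefficients and fit summaries", {
  q <- pon1_model("Q")
  td <- tidy(q)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(td$estimate[td$term == "H8m"], -25.907)
  gl <- glance(q)
  expect_equal(gl$n_terms, 4L)
  expect_equal(gl$provenance, "paper-fixture")
})
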