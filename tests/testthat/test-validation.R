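test_that("fit metrics match hand arithmetic and the perfect-fit limits", {
  # perfect fit
  y <- c(0.3, 1.1, 2.4, 3.2, 4.0)
  fm <- fit_metrics(y, y, p = 1)
  expect_equal(fm$r2, 1)
  expect_equal(fm$rmse, 0)
  expect_equal(fm$mae, 0)
  expect_equal(fm$ccc, 1)
  # hand-computed instance: SStot = 2, SSres = 1
  fm2 <- fit_metrics(c(0, 1, 2), c(0, 1, 3), p = 1)
  expect_equal(fm2$r2, 0.5)
  expect_equal(fm2$rmse, sqrt(1 / 3))
  expect_error(fit_metrics(rep(1, 5), rep(1, 5), p = 1), "variance")
})

test_that("adjusted R2 never exceeds R2 and CCC never exceeds |r|", {
  for (s in 1:10) {
    withr::with_seed(s, {
      y <- stats::rnorm(15)
      yhat <- y * 0.8 + stats::rnorm(15, sd = 0.5)
    })
    fm <- fit_metrics(y, yhat, p = 3)
    expect_lte(fm$r2_adj, fm$r2)
    expect_lte(abs(fm$ccc), abs(stats::cor(y, yhat)) + 1e-12)
  }
})

test_that("closed-form PRESS equals brute-force LOO refitting", {
  # noiseless linear data: Q2 = 1
  withr::with_seed(11, X <- matrix(stats::rnorm(60), 20, 3))
  colnames(X) <- c("a", "b", "c")
  y0 <- as.numeric(2 + X %*% c(1, -2, 0.5))
  expect_equal(q2_loo(X, y0)$q2_loo, 1, tolerance = 1e-9)
  # property: equality with explicit refits across 100 random instances
  for (s in 1:100) {
    withr::with_seed(100 + s, {
      n <- sample(12:25, 1)
      p <- sample(2:4, 1)
      Xs <- matrix(stats::rnorm(n * p), n, p)
      ys <- as.numeric(Xs %*% stats::rnorm(p) + stats::rnorm(n, sd = 0.5))
    })
    colnames(Xs) <- paste0("x", seq_len(p))
    expect_equal(q2_loo(Xs, ys)$q2_loo, q2_loo_oracle(Xs, ys),
                 tolerance = 1e-10)
  }
})

test_that("Q2LOO collapses on scrambled responses against informative descriptors", {
  withr::with_seed(42, {
    X <- matrix(stats::rnorm(90), 30, 3)
    y <- as.numeric(X %*% c(1.5, -1, 1) + stats::rnorm(30, sd = 0.3))
    y_perm <- sample(y)
  })
  colnames(X) <- paste0("x", 1:3)
  expect_gt(q2_loo(X, y)$q2_loo, 0.8)
  expect_lt(q2_loo(X, y_perm)$q2_loo, 0.2)
})

test_that("Q2LMO approaches Q2LOO as the holdout shrinks and is seed-stable", {
  withr::with_seed(5, {
    X <- matrix(stats::rnorm(90), 30, 3)
    y <- as.numeric(X %*% c(1, -1, 0.5) + stats::rnorm(30, sd = 0.4))
  })
  colnames(X) <- paste0("x", 1:3)
  loo <- q2_loo(X, y)$q2_loo
  # smallest admissible holdout (1 compound at n = 30) with many iterations
  lmo_small <- q2_lmo(X, y, leave_fraction = 0.034, iterations = 2000, seed = 9)
  expect_equal(lmo_small$q2_lmo, loo, tolerance = 0.05)
  # determinism
  a <- q2_lmo(X, y, iterations = 50, seed = 7)
  b <- q2_lmo(X, y, iterations = 50, seed = 7)
  expect_identical(a, b)
  expect_error(q2_lmo(X, y, iterations = 0), "iterations")
  expect_error(q2_lmo(X, y, leave_fraction = 0.6), "leave_fraction")
})

test_that("y-scrambling separates signal from chance and is reproducible", {
  sim <- generate_qsar_data(synthetic_spec(
    30, 8, informative = c(d1 = 1, d3 = -1, d5 = 1, d7 = -1),
    intercept = 1, noise_sd = 0.25, seed = 2))
  X <- sim$descriptors[, c("compound_id", sim$truth$informative)]
  sc <- y_scramble(X, sim$y, iterations = 100, seed = 4)
  expect_gt(sc$r2, 0.9)
  expect_lt(sc$mean_r2, 0.3)
  expect_lt(sc$mean_q2, sc$mean_r2)
  # identical seeds give identical distributions
  sc2 <- y_scramble(X, sim$y, iterations = 100, seed = 4)
  expect_identical(sc$runs, sc2$runs)
  expect_error(y_scramble(X, sim$y, iterations = 5), "iterations")
})

test_that("scrambling pure-noise descriptors changes nothing detectable", {
  withr::with_seed(8, {
    X <- matrix(stats::rnorm(30 * 4), 30, 4)
    y <- stats::rnorm(30)
  })
  colnames(X) <- paste0("x", 1:4)
  sc <- y_scramble(X, y, iterations = 200, seed = 3)
  # unscrambled R2 sits inside the scrambled distribution
  expect_gt(mean(sc$runs$r2 >= sc$r2), 0.05)
})

test_that("the full validation report reproduces its published-style roster", {
  sim <- pon1_like(seed = 6)
  split <- ordered_split(sim$y)
  rep <- validate_model(sim$descriptors, sim$y, split = split,
                        descriptors = sim$truth$informative,
                        lmo_iterations = 200, seed = 2)
  expect_s3_class(rep, "qsar_validation")
  expect_equal(rep$n_train, 24)
  expect_equal(rep$n_test, 6)
  expect_equal(rep$p, 4)
  expect_true(rep$fitting$r2 >= 0 && rep$fitting$r2 <= 1)
  expect_lte(rep$fitting$r2_adj, rep$fitting$r2)
  expect_gte(rep$fitting$rmse, 0)
  expect_true(abs(rep$fitting$ccc) <= 1)
  expect_false(is.null(rep$external))
  # long tidy form covers the three blocks
  td <- tidy(rep)
  expect_setequal(unique(td$block), c("fitting", "internal", "external"))
  # glance gives the headline row
  expect_named(glance(rep),
               c("r2_tr", "r2_adj", "rmse_tr", "q2_loo", "q2_lmo",
                 "n_train", "n_test", "p", "r2_ext", "rmse_ext"))
  # serialization
  path <- withr::local_tempfile(fileext = ".json")
  write_validation(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$fitting$r2, rep$fitting$r2, tolerance = 1e-12)
})

test_that("training-mean centering is available for external R2", {
  sim <- pon1_like(seed = 9)
  split <- ordered_split(sim$y)
  a <- validate_model(sim$descriptors, sim$y, split = split,
                      descriptors = sim$truth$informative,
                      lmo_iterations = 50)
  b <- validate_model(sim$descriptors, sim$y, split = split,
                      descriptors = sim$truth$informative,
                      lmo_iterations = 50, external_center = "training")
  expect_false(isTRUE(all.equal(a$external$r2_ext, b$external$r2_ext)))
})
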