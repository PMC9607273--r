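test_that("the generator plants an exactly recoverable signal at zero noise", {
  spec <- synthetic_spec(25, 10, informative = c(d2 = 1.5, d7 = -0.75),
                         intercept = 2, noise_sd = 0, seed = 8)
  sim <- generate_qsar_data(spec)
  m <- fit_mlr(sim$descriptors, sim$y, descriptors = c("d2", "d7"))
  expect_equal(m$intercept, 2, tolerance = 1e-10)
  expect_equal(unname(m$terms), c(1.5, -0.75), tolerance = 1e-10)
  # determinism
  sim2 <- generate_qsar_data(spec)
  expect_identical(sim$descriptors, sim2$descriptors)
  expect_identical(sim$y, sim2$y)
})

test_that("correlated blocks reach their target correlation and feed the filter", {
  # empirical correlation within 0.05 of target at large n
  spec <- synthetic_spec(400, 6, informative = c(d6 = 1), noise_sd = 0.1,
                         correlated_blocks = list(list(columns = 1:3, rho = 0.8)),
                         seed = 12)
  sim <- generate_qsar_data(spec)
  m <- as.matrix(as.data.frame(sim$descriptors)[-1])
  cors <- stats::cor(m[, 1:3])
  expect_true(all(abs(cors[upper.tri(cors)] - 0.8) < 0.05))
  # a 0.99-correlated 4-column block leaves one survivor at the 0.95 filter
  spec2 <- synthetic_spec(60, 10, informative = c(d9 = 1), noise_sd = 0.2,
                          correlated_blocks = list(list(columns = 1:4, rho = 0.99)),
                          seed = 13)
  sim2 <- generate_qsar_data(spec2)
  kept <- setdiff(names(drop_correlated(sim2$descriptors, 0.95)), "compound_id")
  expect_length(intersect(kept, c("d1", "d2", "d3", "d4")), 1)
  # infeasible correlation structure errors
  expect_error(generate_qsar_data(synthetic_spec(
    10, 4, informative = c(d4 = 1),
    correlated_blocks = list(list(columns = 1:3, rho = -0.9)))),
    "positive definite")
})

test_that("coefficient estimates concentrate on the truth as noise vanishes", {
  bias <- vapply(c(0.5, 0.1, 0.01), function(sdn) {
    errs <- vapply(1:10, function(s) {
      sim <- generate_qsar_data(synthetic_spec(
        40, 8, informative = c(d1 = 1, d5 = -1), noise_sd = sdn, seed = s))
      m <- fit_mlr(sim$descriptors, sim$y, descriptors = c("d1", "d5"))
      mean(abs(unname(m$terms) - c(1, -1)))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
  expect_lt(bias[3], 0.005)
})

test_that("the PON1-sized preset has the advertised shape and split", {
  sim <- pon1_like(seed = 1)
  expect_equal(dim(sim$descriptors), c(30, 101))
  expect_length(sim$y, 30)
  expect_length(sim$truth$informative, 4)
  sp <- ordered_split(sim$y, 5)
  expect_length(sp$train, 24)
  expect_length(sp$test, 6)
  # truth record serializes
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(sim, path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(js$informative, sim$truth$informative)
})

test_that("spec validation rejects out-of-range inputs", {
  expect_error(synthetic_spec(10, 5, informative = c(d7 = 1)), "1..n_descriptors")
  expect_error(synthetic_spec(10, 5, informative = c(d1 = 1), noise_sd = -1),
               "noise_sd")
  expect_error(synthetic_spec(10, 5, informative = c(d1 = 1),
                              correlated_blocks = list(list(columns = 1:2, rho = 1))),
               "correlations")
})
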