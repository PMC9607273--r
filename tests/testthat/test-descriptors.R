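# Descriptor operators checked against closed forms, independent brute-force
# oracles, and their rigid-motion invariance contracts.

test_that("3D-MoRSE matches closed forms and the brute-force pair loop", {
  # signal 1 is the s -> 0 limit: sum of pairwise weight products
  g <- random_geometry(n = 6, seed = 2)
  props <- atomic_properties()
  w <- props$w_mass[match(g$elements, props$element)]
  expect_equal(morse(g, 1, "mass"), sum((w %o% w)[upper.tri(diag(6))]))
  # two unit-weight atoms 1 Angstrom apart at s = 1: sin(1)/1
  pair <- geometry(matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                   c("C", "C"))
  expect_equal(morse(pair, 2, "unweighted"), sin(1), tolerance = 1e-12)
  # property: equality with the independent double loop on random geometries
  for (s in 1:8) {
    g <- random_geometry(n = 4 + s, seed = 10 + s)
    idx <- 1 + (s * 3) %% 32
    expect_equal(morse(g, idx, "mass"), morse_oracle(g, idx, "mass"),
                 tolerance = 1e-12)
  }
  expect_error(morse(g, 0), "1..32")
  expect_error(morse(g, 33), "1..32")
})

test_that("WHIM E1 matches an explicit eigen-decomposition oracle", {
  g <- random_geometry(n = 9, seed = 5)
  # unit weights: direct unweighted PCA + inverse kurtosis
  M <- sweep(g$coords, 2, colMeans(g$coords))
  ev <- eigen(stats::cov(M) * (nrow(M) - 1) / nrow(M), symmetric = TRUE)
  t1 <- M %*% ev$vectors[, 1]
  oracle <- ev$values[1]^2 * nrow(M) / sum(t1^4)
  expect_equal(whim_E1(g, "unweighted"), oracle, tolerance = 1e-10)
  expect_gt(whim_E1(g, "vdw_volume"), 0)
})

test_that("3D descriptors are invariant under rigid rotation and translation", {
  for (s in 1:6) {
    g <- random_geometry(n = 7 + s %% 3, seed = 20 + s)
    gt <- pon1qsar:::transform_geometry(g, random_rotation(s), c(5, 5, 5))
    expect_equal(morse(gt, 10, "mass"), morse(g, 10, "mass"),
                 tolerance = 1e-9)
    expect_equal(whim_E1(gt, "vdw_volume"), whim_E1(g, "vdw_volume"),
                 tolerance = 1e-9)
    expect_equal(getaway_H(gt, 3), getaway_H(g, 3), tolerance = 1e-9)
  }
})

test_that("degenerate geometries are rejected by the 3D operators", {
  line <- geometry(cbind(seq(0, 4.5, by = 1.5), 0, 0), rep("C", 4),
                   bonds = cbind(1:3, 2:4))
  expect_error(whim_E1(line), "[Dd]egenerate")
  expect_error(influence_matrix(line), "[Rr]ank")
})

test_that("GETAWAY H matches the brute-force oracle and its projection trace", {
  skip_if_no_embedding()
  # influence matrix is a rank-3 projection for any non-planar geometry
  g <- random_geometry(n = 9, seed = 31)
  expect_equal(sum(diag(influence_matrix(g))), 3, tolerance = 1e-9)
  # gamma-butyrolactone: heavy-atom graph diameter < 8, so H8m = 0
  gbl <- cached_conformer("C1CC(=O)OC1")
  expect_equal(getaway_H(gbl, 8), 0)
  # undecano-gamma-lactone: long chain, lag 8 reachable; brute-force equality
  undec <- cached_conformer("CCCCCCCC1CCC(=O)O1")
  expect_gt(getaway_H(undec, 8), 0)
  expect_equal(getaway_H(undec, 8), getaway_oracle(undec, 8),
               tolerance = 1e-12)
  # and on random chain geometries at several lags
  for (s in 1:4) {
    g <- random_geometry(n = 10, seed = 40 + s)
    expect_equal(getaway_H(g, s + 1), getaway_oracle(g, s + 1),
                 tolerance = 1e-12)
  }
})

test_that("SIC0 spans its closed-form range and matches the hand entropy", {
  # all one element -> 0
  g1 <- random_geometry(n = 5, seed = 50)
  g1$elements <- rep("C", 5)
  expect_equal(sic0(g1), 0)
  # every atom distinct -> 1
  g2 <- random_geometry(n = 5, seed = 51)
  g2$elements <- c("C", "N", "O", "S", "H")
  expect_equal(sic0(g2), 1)
  # gamma-butyrolactone: classes {C:4, H:6, O:2} of 12 atoms
  p <- c(4, 6, 2) / 12
  expected <- -sum(p * log2(p)) / log2(12)
  skip_if_no_embedding()
  expect_equal(sic0(cached_conformer("C1CC(=O)OC1")), expected,
               tolerance = 1e-12)
})

test_that("descriptor matrices are computed per spec with provenance", {
  skip_if_no_embedding()
  pon1 <- head(pon1_dataset(), 6)
  X <- compute_descriptor_matrix(pon1, c("Mor10m", "Mor17m", "E1v", "SIC0"),
                                 seed = 3)
  expect_equal(dim(X), c(6, 5))
  expect_false(anyNA(X))
  expect_equal(X$compound_id, pon1$id)
  expect_equal(unname(attr(X, "provenance")), rep("computed", 4))
  # reproducible given the seed
  X2 <- compute_descriptor_matrix(pon1, c("Mor10m", "Mor17m", "E1v", "SIC0"),
                                  seed = 3)
  expect_identical(as.data.frame(X), as.data.frame(X2))
  # user-supplied extra columns pass through with provenance
  extra <- tibble::tibble(compound_id = pon1$id, homo_energy = seq(0.1, 0.6, 0.1))
  X3 <- compute_descriptor_matrix(pon1, c("SIC0", "homo_energy"), seed = 3,
                                  extra_columns = extra)
  expect_equal(attr(X3, "provenance")[["homo_energy"]], "user-supplied")
  expect_equal(X3$homo_energy, extra$homo_energy)
})

test_that("descriptor-matrix errors name the offending input", {
  pon1 <- head(pon1_dataset(), 4)
  expect_error(compute_descriptor_matrix(pon1, character(0)), "at least one")
  expect_error(compute_descriptor_matrix(pon1, c("E1v", "E1v")), "Duplicate")
  expect_error(compute_descriptor_matrix(pon1, "NotADescriptor"),
               "NotADescriptor")
})

test_that("descriptor matrices round-trip through delimited text", {
  X <- tibble::tibble(compound_id = c("a", "b", "c"),
                      Mor10m = c(0.1, -0.2, 0.3), E1v = c(0.4, 0.5, 0.6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_matrix(X, path)
  back <- read_descriptor_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(X))
})
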