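# Shared helpers: random geometries built in code, independent oracles, and
# small fixture constructors.

# A random point-cloud geometry with a chain bond graph, guaranteed to have
# no near-coincident atoms. Elements drawn from common organics.
random_geometry <- function(n = 8, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      coords <- matrix(stats::runif(n * 3, -4, 4), n, 3)
      if (n < 2 || min(stats::dist(coords)) >= 0.6) break
    }
    elements <- sample(c("C", "N", "O", "S", "H"), n, replace = TRUE)
    bonds <- cbind(seq_len(n - 1), seq(2, n))
    geometry(coords, elements, bonds, validate = FALSE)
  })
}

# Random 3D rotation matrix via QR of a Gaussian matrix (det forced to +1).
random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
    R <- qr.Q(qr_dec)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

# Independent brute-force 3D-MoRSE oracle: double loop over all pairs.
morse_oracle <- function(geom, signal_index, weighting = "mass") {
  s <- signal_index - 1
  w <- if (weighting == "mass") {
    props <- atomic_properties()
    props$w_mass[match(geom$elements, props$element)]
  } else rep(1, nrow(geom$coords))
  n <- nrow(geom$coords)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2))
      term <- if (s == 0) 1 else sin(s * r) / (s * r)
      total <- total + w[i] * w[j] * term
    }
  }
  total
}

# Independent shortest-path routine (Floyd-Warshall) for the GETAWAY oracle.
floyd_warshall <- function(n, edges) {
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    D[edges[k, 1], edges[k, 2]] <- 1
    D[edges[k, 2], edges[k, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Brute-force GETAWAY H oracle: explicit influence matrix + Floyd-Warshall
# distances, independent of the package's BFS and loop structure.
getaway_oracle <- function(geom, lag) {
  M <- sweep(geom$coords, 2, colMeans(geom$coords))
  H <- M %*% solve(t(M) %*% M) %*% t(M)
  D <- floyd_warshall(nrow(M), geom$bonds)
  props <- atomic_properties()
  w <- props$w_mass[match(geom$elements, props$element)]
  total <- 0
  n <- nrow(M)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] == lag && H[i, j] > 0) total <- total + H[i, j] * w[i] * w[j]
  }
  total
}

# Explicit leave-one-out refitting oracle for Q2.
q2_loo_oracle <- function(X, y) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    b <- qr.coef(qr(cbind(1, X[-i, , drop = FALSE])), y[-i])
    press <- press + (y[i] - sum(c(1, X[i, ]) * b))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Write a compound table string to a temp file and return the path.
write_table_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

skip_if_no_openbabel <- function() {
  testthat::skip_if_not(nzchar(Sys.which("obabel")),
                        "OpenBabel not available")
}

skip_if_no_embedding <- function() {
  testthat::skip_if_not(pon1qsar:::has_embedding_backend(),
                        "No conformer-embedding backend (python + RDKit)")
}

# Cache embedded conformers across tests within a session (embedding is
# deterministic, so this is purely a speed measure).
.geom_cache <- new.env(parent = emptyenv())
cached_conformer <- function(smiles, seed = 7) {
  key <- paste0(smiles, "#", seed)
  if (is.null(.geom_cache[[key]])) {
    .geom_cache[[key]] <- embed_conformer(smiles, seed = seed)
  }
  .geom_cache[[key]]
}
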