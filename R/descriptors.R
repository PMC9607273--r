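# 3D molecular descriptor operators: the families appearing in the published
# four-variable PON1 models. Each operator takes a qsar_geometry and returns
# a scalar; all are invariant to rigid rotation and translation.

#' 3D-MoRSE signal
#'
#' The 3D Molecule Representation of Structures based on Electron diffraction
#' descriptor: for scattering parameter `s`,
#' \deqn{Mor(s)_w = \sum_{i<j} w_i w_j \frac{\sin(s\, r_{ij})}{s\, r_{ij}},}
#' summed over all atom pairs at interatomic distance \eqn{r_{ij}}
#' (Angstrom), with each sinc term equal to 1 at `s = 0`. Signal index `k`
#' corresponds to \eqn{s = k - 1} reciprocal Angstrom, so index 1 is the
#' \eqn{s \to 0} limit — the convention of the descriptor software that
#' popularized the family (`Mor10m` is signal index 10 weighted by mass).
#' Weights are atomic properties scaled to carbon = 1; hydrogens are
#' included (their mass weight is ~0.08, so they contribute little when
#' mass-weighted, which is precisely why the mass weighting emphasizes
#' heavy-atom topology).
#'
#' @param geom A `qsar_geometry` with at least 2 atoms.
#' @param signal_index Integer in 1..32.
#' @param weighting `"mass"` (default) or `"unweighted"`.
#' @return A finite scalar.
#' @export
morse <- function(geom, signal_index, weighting = c("mass", "unweighted")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(geom, "qsar_geometry"))
  n <- nrow(geom$coords)
  if (n < 2) abort("3D-MoRSE needs at least 2 atoms")
  if (!is.numeric(signal_index) || length(signal_index) != 1 ||
      signal_index < 1 || signal_index > 32 || signal_index %% 1 != 0) {
    abort("`signal_index` must be an integer in 1..32")
  }
  s <- signal_index - 1
  w <- atom_weights(geom$elements, weighting)
  d <- as.matrix(stats::dist(geom$coords))
  iu <- upper.tri(d)
  r <- d[iu]
  ww <- (w %o% w)[iu]
  if (s == 0) {
    sum(ww)
  } else {
    sum(ww * sin(s * r) / (s * r))
  }
}

#' WHIM first-axis accessibility (inverse kurtosis) index
#'
#' Weighted Holistic Invariant Molecular descriptor `E1`: atoms are centered
#' at their weighted centroid, the weighted covariance of the coordinates is
#' eigen-decomposed, atom scores `t` are the projections on the first
#' principal axis, and
#' \deqn{E_1 = \frac{\lambda_1^2 \sum_i w_i}{\sum_i w_i t_{i1}^4},}
#' the weighted inverse kurtosis of the first-axis scores
#' (\eqn{\lambda_1} is the leading eigenvalue, i.e. the weighted score
#' variance). Large values indicate scores spread away from the axis center
#' — a directional "accessibility" of the molecule along its principal
#' extension. `E1v` is this index with van-der-Waals-volume weights.
#'
#' @param geom A `qsar_geometry` with at least 4 non-collinear atoms.
#' @param weighting `"vdw_volume"` (default, the published model's `E1v`),
#'   `"mass"`, or `"unweighted"`.
#' @return A finite positive scalar, invariant to rigid motion.
#' @export
whim_E1 <- function(geom, weighting = c("vdw_volume", "mass", "unweighted")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(geom, "qsar_geometry"))
  n <- nrow(geom$coords)
  if (n < 4) abort("WHIM needs at least 4 atoms")
  w <- atom_weights(geom$elements, weighting)
  ctr <- colSums(geom$coords * w) / sum(w)
  M <- sweep(geom$coords, 2, ctr)
  S <- crossprod(M * w, M) / sum(w)
  eig <- eigen(S, symmetric = TRUE)
  lambda1 <- eig$values[1]
  if (lambda1 < 1e-12) abort("Degenerate geometry: zero variance along every axis")
  if (eig$values[2] < 1e-10 * lambda1) {
    abort("Degenerate geometry: collinear atoms (no variance off the first axis)")
  }
  t1 <- as.numeric(M %*% eig$vectors[, 1])
  if (stats::weighted.mean(t1^2, w) < 1e-12) {
    abort("Degenerate geometry: zero first-axis score variance")
  }
  m4 <- sum(w * t1^4)
  if (m4 < 1e-300) abort("Degenerate geometry: collinear atoms")
  lambda1^2 * sum(w) / m4
}

#' Molecular influence matrix of a geometry
#'
#' The GETAWAY influence matrix \eqn{H = M (M^T M)^{-1} M^T} built from the
#' centered coordinate matrix `M`. It is the orthogonal projection onto the
#' column space of the centered coordinates, so its diagonal sums to the
#' coordinate rank (3 for any non-planar molecule); diagonal elements play
#' the role of atomic leverages on the molecular geometry.
#'
#' @param geom A `qsar_geometry` with at least 4 atoms.
#' @return An n-by-n numeric matrix.
#' @export
influence_matrix <- function(geom) {
  stopifnot(inherits(geom, "qsar_geometry"))
  n <- nrow(geom$coords)
  if (n < 4) abort("GETAWAY needs at least 4 atoms")
  M <- sweep(geom$coords, 2, colMeans(geom$coords))
  MtM <- crossprod(M)
  if (rcond(MtM) < 1e-12) {
    abort("Rank-deficient coordinate matrix (planar or collinear geometry)")
  }
  M %*% solve(MtM, t(M))
}

#' GETAWAY H autocorrelation
#'
#' \deqn{H_k(w) = \sum_{i<j : d_{ij} = k,\ h_{ij} > 0} h_{ij} w_i w_j,}
#' the sum of positive off-diagonal influence-matrix elements over atom pairs
#' at topological (bond-graph) distance `k`, property-weighted. `H8m` is lag
#' 8 with mass weights. Returns 0 when the graph diameter is below the lag.
#' Distances are computed on the hydrogen-included bond graph; restricting
#' the sum to positive \eqn{h_{ij}} follows the published GETAWAY
#' definition (set `positive_only = FALSE` to keep all elements).
#'
#' @param geom A `qsar_geometry` with a connected bond graph.
#' @param lag Topological distance, integer >= 1.
#' @param weighting `"mass"` (default) or `"unweighted"`.
#' @param positive_only Keep only `h_ij > 0` terms (default `TRUE`).
#' @return A finite non-negative scalar (when `positive_only = TRUE`).
#' @export
getaway_H <- function(geom, lag, weighting = c("mass", "unweighted"),
                      positive_only = TRUE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(geom, "qsar_geometry"))
  if (!is.numeric(lag) || length(lag) != 1 || lag < 1 || lag %% 1 != 0) {
    abort("`lag` must be an integer >= 1")
  }
  n <- nrow(geom$coords)
  if (nrow(geom$bonds) == 0) abort("GETAWAY needs the molecular bond graph")
  H <- influence_matrix(geom)
  D <- topological_distances(n, geom$bonds)
  w <- atom_weights(geom$elements, weighting)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] == lag && (!positive_only || H[i, j] > 0)) {
        total <- total + H[i, j] * w[i] * w[j]
      }
    }
  }
  total
}

#' Structural information content of order 0
#'
#' Atoms (hydrogens included) are partitioned into equivalence classes by
#' element; `IC0` is the Shannon entropy of the class-size distribution in
#' bits, and `SIC0` normalizes it by its maximum `log2(n_atoms)`:
#' \deqn{SIC_0 = \frac{-\sum_c p_c \log_2 p_c}{\log_2 A} \in [0, 1],}
#' 0 for a homoatomic molecule, 1 when every atom is a distinct element.
#'
#' @param geom A `qsar_geometry` with at least 2 atoms.
#' @return A scalar in \[0, 1\].
#' @export
sic0 <- function(geom) {
  stopifnot(inherits(geom, "qsar_geometry"))
  n <- length(geom$elements)
  if (n < 2) abort("SIC0 needs at least 2 atoms")
  p <- as.numeric(table(geom$elements)) / n
  ic0 <- -sum(p * log2(p))
  ic0 / log2(n)
}

# Registry mapping descriptor-name patterns to operator closures. Names
# follow the established descriptor nomenclature: MorXXm / MorXXu (3D-MoRSE
# signal XX, mass / unit weighted), E1v / E1m, HXm (GETAWAY H lag X, mass),
# SIC0.
descriptor_function <- function(name) {
  if (grepl("^Mor[0-9]{2}[mu]$", name)) {
    idx <- as.integer(substr(name, 4, 5))
    wt <- if (substr(name, 6, 6) == "m") "mass" else "unweighted"
    if (idx >= 1 && idx <= 32) {
      return(function(geom) morse(geom, idx, wt))
    }
  }
  if (name == "E1v") return(function(geom) whim_E1(geom, "vdw_volume"))
  if (name == "E1m") return(function(geom) whim_E1(geom, "mass"))
  if (grepl("^H[0-9]+m$", name)) {
    lag <- as.integer(sub("^H([0-9]+)m$", "\\1", name))
    if (lag >= 1) return(function(geom) getaway_H(geom, lag, "mass"))
  }
  if (name == "SIC0") return(function(geom) sic0(geom))
  NULL
}

#' Names of descriptors this package can compute
#' @return Character vector of computable descriptor names.
#' @export
known_descriptors <- function() {
  c(sprintf("Mor%02dm", 1:32), sprintf("Mor%02du", 1:32),
    "E1v", "E1m", sprintf("H%dm", 1:10), "SIC0")
}

#' Compute a descriptor matrix for a compound set
#'
#' Embeds one conformer per compound ([embed_conformer()]) and evaluates the
#' requested descriptors, returning a tidy matrix: one row per compound, one
#' column per descriptor, `compound_id` first. Columns named in
#' `extra_columns` are taken from that table instead of being computed
#' (user-supplied descriptors such as quantum-chemical quantities); column
#' provenance is recorded in the `"provenance"` attribute.
#'
#' @param tbl A compound table (`id`, `smiles`, ...).
#' @param descriptors Character vector of descriptor names; each must be
#'   computable ([known_descriptors()]) or present in `extra_columns`.
#' @param seed Integer embedding seed (recorded per geometry).
#' @param extra_columns Optional data frame of user-supplied descriptor
#'   columns with a `compound_id` (or `id`) column.
#' @param geometries Optional named list of pre-built `qsar_geometry`
#'   objects keyed by compound id (e.g. from SDF input); compounds present
#'   here are not re-embedded.
#' @return A tibble (`qsar_descriptors`) with attributes `provenance`
#'   (named character, `"computed"` or `"user-supplied"`) and `constant`
#'   (names of zero-variance columns, flagged but kept).
#' @export
#' @examples
#' \dontrun{
#' pon1 <- pon1_dataset()
#' X <- compute_descriptor_matrix(pon1, c("Mor10m", "Mor17m", "E1v", "H8m"))
#' }
compute_descriptor_matrix <- function(tbl, descriptors, seed = 1L,
                                      extra_columns = NULL,
                                      geometries = NULL) {
  if (length(descriptors) == 0) abort("`descriptors` must name at least one descriptor")
  if (anyDuplicated(descriptors)) {
    abort(paste0("Duplicate descriptor name(s): ",
                 paste(unique(descriptors[duplicated(descriptors)]),
                       collapse = ", ")))
  }
  ids <- if ("id" %in% names(tbl)) tbl$id
         else if ("compound_id" %in% names(tbl)) tbl$compound_id
         else abort("Compound table needs an `id` column")
  extra <- NULL
  if (!is.null(extra_columns)) {
    extra <- as_tibble(extra_columns)
    key <- intersect(c("compound_id", "id"), names(extra))[1]
    if (is.na(key)) abort("`extra_columns` needs a compound_id (or id) column")
    extra <- extra[match(ids, extra[[key]]), , drop = FALSE]
  }
  fns <- lapply(descriptors, descriptor_function)
  supplied <- !is.na(match(descriptors, names(extra) %||% character(0)))
  unknown <- descriptors[vapply(fns, is.null, logical(1)) & !supplied]
  if (length(unknown) > 0) {
    abort(paste0("Unknown descriptor name(s): ",
                 paste(unknown, collapse = ", "),
                 ". Computable descriptors: ",
                 paste(known_descriptors(), collapse = ", ")))
  }
  computed <- descriptors[!supplied]
  geoms <- NULL
  if (length(computed) > 0) {
    geoms <- vector("list", length(ids))
    names(geoms) <- ids
    have <- intersect(ids, names(geometries) %||% character(0))
    geoms[have] <- geometries[have]
    need <- setdiff(ids, have)
    if (length(need) > 0) {
      rows <- match(need, ids)
      geoms[need] <- embed_conformers(
        tibble(id = need, smiles = tbl$smiles[rows]), seed = seed)
    }
  }
  vals <- lapply(seq_along(descriptors), function(k) {
    nm <- descriptors[k]
    if (supplied[k]) {
      v <- extra[[nm]]
      if (anyNA(v)) abort(paste0("User-supplied column ", nm, " has missing values"))
      as.numeric(v)
    } else {
      vapply(geoms, fns[[k]], numeric(1))
    }
  })
  out <- as_tibble(setNames(vals, descriptors))
  out <- dplyr::bind_cols(tibble(compound_id = ids), out)
  attr(out, "provenance") <- setNames(
    ifelse(supplied, "user-supplied", "computed"), descriptors)
  const <- descriptors[vapply(vals, function(v) stats::sd(v) == 0, logical(1))]
  if (length(const) > 0) {
    warn(paste0("Constant descriptor column(s): ", paste(const, collapse = ", ")))
  }
  attr(out, "constant") <- const
  class(out) <- c("qsar_descriptors", class(out))
  out
}

#' Read / write a descriptor matrix as delimited text
#'
#' Compounds as rows, header of descriptor names, `compound_id` first.
#'
#' @param path File path.
#' @param delim Delimiter (comma default, tab accepted).
#' @return `read_descriptor_matrix()`: a tibble with `compound_id` plus
#'   numeric descriptor columns. `write_descriptor_matrix()`: `path`,
#'   invisibly.
#' @export
read_descriptor_matrix <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("Descriptor matrix not found: ", path))
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!"compound_id" %in% names(out)) {
    names(out)[1] <- "compound_id"
  }
  num_cols <- setdiff(names(out), "compound_id")
  bad <- num_cols[!vapply(out[num_cols], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric descriptor column(s): ", paste(bad, collapse = ", ")))
  }
  if (anyNA(out[num_cols])) abort("Descriptor matrix has missing values")
  out
}

#' @rdname read_descriptor_matrix
#' @param x A descriptor tibble (`compound_id` + numeric columns).
#' @export
write_descriptor_matrix <- function(x, path, delim = ",") {
  readr::write_delim(as_tibble(as.data.frame(x)), path, delim = delim)
  invisible(path)
}

# Strip the id column and return the numeric matrix, preserving order.
descriptor_values <- function(x) {
  cols <- setdiff(names(x), "compound_id")
  m <- as.matrix(as.data.frame(x)[cols])
  rownames(m) <- x$compound_id
  m
}
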