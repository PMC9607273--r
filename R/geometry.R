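# Conformer geometries and the atomic property table behind descriptor
# weighting schemes.

# Atomic masses (u) and van-der-Waals radii (Angstrom, Bondi) for the
# elements that occur in PON1 substrates plus common organics. vdW volumes
# are the sphere volumes 4/3*pi*r^3. Weighting schemes used by the 3D
# descriptors are these properties scaled to carbon = 1, the convention of
# the descriptor literature (so hydrogens contribute little to mass-weighted
# signals and halogens a lot).
.atomic_properties <- local({
  tab <- data.frame(
    element = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
    mass = c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998,
             28.086, 30.974, 32.06, 35.453, 79.904, 126.904),
    vdw_radius = c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47,
                   2.10, 1.80, 1.80, 1.75, 1.85, 1.98)
  )
  tab$vdw_volume <- 4 / 3 * pi * tab$vdw_radius^3
  tab
})

#' Atomic property table used for descriptor weighting
#'
#' @return A tibble with one row per supported element: `element`, `mass`
#'   (u), `vdw_radius` (Angstrom, Bondi), `vdw_volume` (Angstrom^3), and the
#'   carbon-scaled weights `w_mass`, `w_vdw` actually used by the weighted
#'   descriptors.
#' @export
atomic_properties <- function() {
  tab <- .atomic_properties
  c_row <- tab[tab$element == "C", ]
  as_tibble(dplyr::mutate(tab,
    w_mass = .data$mass / c_row$mass,
    w_vdw = .data$vdw_volume / c_row$vdw_volume
  ))
}

atom_weights <- function(elements, weighting = c("mass", "vdw_volume", "unweighted")) {
  weighting <- match.arg(weighting)
  if (weighting == "unweighted") return(rep(1, length(elements)))
  props <- atomic_properties()
  idx <- match(elements, props$element)
  if (anyNA(idx)) {
    abort(paste0("No atomic properties for element(s): ",
                 paste(unique(elements[is.na(idx)]), collapse = ", ")))
  }
  if (weighting == "mass") props$w_mass[idx] else props$w_vdw[idx]
}

#' Construct a conformer geometry object
#'
#' A geometry couples per-atom 3D coordinates with the element labels, atomic
#' masses, van-der-Waals volumes and the molecular bond graph — everything the
#' 3D descriptor operators need. Usually produced by [embed_conformer()] or
#' [read_sdf_geometry()]; exposed directly so synthetic geometries can be
#' built in tests and simulations.
#'
#' @param coords Numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param elements Character vector of element symbols, one per atom.
#' @param bonds Two-column integer matrix of 1-based atom indices (undirected
#'   edges); may have zero rows for a bond-free point cloud (descriptors that
#'   need the graph will refuse it).
#' @param embed_seed Integer recorded as the geometry's embedding seed.
#' @param validate If `TRUE`, check finiteness, minimum interatomic distance
#'   (0.5 Angstrom) and connectivity of the bond graph.
#' @return An object of class `qsar_geometry`.
#' @export
geometry <- function(coords, elements, bonds = matrix(integer(0), ncol = 2),
                     embed_seed = NA_integer_, validate = TRUE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) abort("`coords` must have 3 columns (x, y, z)")
  n <- nrow(coords)
  if (length(elements) != n) {
    abort("`elements` must have one symbol per coordinate row")
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  g <- structure(
    list(coords = coords, elements = as.character(elements), bonds = bonds,
         mass = atomic_properties()$mass[
           match(elements, atomic_properties()$element)],
         vdw_volume = atomic_properties()$vdw_volume[
           match(elements, atomic_properties()$element)],
         embed_seed = as.integer(embed_seed)),
    class = "qsar_geometry")
  if (validate) validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  if (!all(is.finite(g$coords))) abort("Geometry has non-finite coordinates")
  n <- nrow(g$coords)
  if (n >= 2) {
    d <- stats::dist(g$coords)
    if (min(d) < 0.5) {
      abort("Geometry has atoms closer than 0.5 Angstrom")
    }
  }
  if (nrow(g$bonds) > 0) {
    if (max(g$bonds) > n || min(g$bonds) < 1) {
      abort("Bond indices out of range")
    }
    comp <- graph_components(n, g$bonds)
    if (length(unique(comp)) > 1) {
      abort("Bond graph is disconnected: geometry must be a single molecule")
    }
  }
  invisible(g)
}

#' @export
print.qsar_geometry <- function(x, ...) {
  cat(sprintf("<qsar_geometry> %d atoms (%s), %d bonds\n",
              nrow(x$coords),
              paste(names(sort(-table(x$elements))), collapse = ","),
              nrow(x$bonds)))
  invisible(x)
}

# Connected components of an undirected graph by label propagation.
graph_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# All-pairs shortest path lengths (unweighted) on the bond graph, by BFS from
# each atom. Small molecules only; complexity O(n * edges) is irrelevant here.
topological_distances <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(D[s, nxt])]
      D[s, nxt] <- depth
      frontier <- nxt
    }
  }
  D
}

embedding_helper <- function() {
  system.file("python", "embed_conformers.py", package = "pon1qsar",
              mustWork = TRUE)
}

has_embedding_backend <- function() {
  nzchar(Sys.which("python")) &&
    suppressWarnings(system2("python", c("-c", shQuote("import rdkit")),
                             stdout = FALSE, stderr = FALSE)) == 0
}

#' Embed 3D conformers from SMILES strings
#'
#' Generates one low-energy 3D conformer per compound by distance-geometry
#' embedding (ETKDG, via the RDKit toolkit's Python interface) followed by
#' MMFF94 force-field minimization, with explicit hydrogens. The embedding
#' is deterministic given `seed`: the same structure string and seed always
#' yield the same coordinates, so descriptor values are reproducible
#' bit-for-bit.
#'
#' Geometries produced this way stand in for the molecular-mechanics
#' minimized structures used when the published models were trained;
#' conformer provenance shifts 3D descriptor values, which is why downstream
#' validation statistics are checked as properties rather than reproduced
#' digit-by-digit.
#'
#' `embed_conformers()` embeds a whole compound table in one helper call
#' (much faster than per-compound calls); `embed_conformer()` is the
#' single-structure convenience wrapper.
#'
#' @param tbl A compound table with `id` and `smiles` columns.
#' @param smiles A single structure string.
#' @param seed Integer random seed for the distance-geometry embedding.
#' @param compound_id Optional label used in error messages.
#' @return `embed_conformers()`: a named list of `qsar_geometry` objects
#'   keyed by compound id, in table order. `embed_conformer()`: a single
#'   `qsar_geometry`.
#' @export
#' @examples
#' \dontrun{
#' g <- embed_conformer("C1CC(=O)OC1", seed = 7) # gamma-butyrolactone, 12 atoms
#' }
embed_conformers <- function(tbl, seed = 1L) {
  ids <- if ("id" %in% names(tbl)) tbl$id else tbl$compound_id
  smiles <- tbl$smiles
  stopifnot(!is.null(ids), !is.null(smiles))
  bad <- which(is.na(smiles) | !nzchar(smiles))
  if (length(bad) > 0) {
    abort(paste0("Invalid structure string for ", paste(ids[bad], collapse = ", ")))
  }
  if (!has_embedding_backend()) {
    abort(paste0("Conformer embedding needs `python` with the RDKit toolkit ",
                 "on PATH"))
  }
  infile <- tempfile(fileext = ".tsv")
  outfile <- tempfile(fileext = ".sdf")
  errfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile, errfile)), add = TRUE)
  writeLines(paste(ids, smiles, sep = "\t"), infile)
  status <- suppressWarnings(system2(
    "python", c(embedding_helper(), shQuote(infile), as.integer(seed),
                shQuote(outfile)),
    stdout = FALSE, stderr = errfile))
  if (status != 0) {
    msg <- tryCatch(paste(readLines(errfile), collapse = " "),
                    error = function(e) "")
    abort(paste0("Conformer embedding failed",
                 if (nzchar(msg)) paste0(": ", msg) else ""))
  }
  geoms <- read_sdf_geometries(outfile, embed_seed = seed)
  missing <- setdiff(ids, names(geoms))
  if (length(missing) > 0) {
    abort(paste0("Conformer embedding failed for compound ",
                 paste(missing, collapse = ", ")))
  }
  geoms[ids]
}

#' @rdname embed_conformers
#' @export
embed_conformer <- function(smiles, seed = 1L, compound_id = NULL) {
  label <- compound_id %||% smiles
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) {
    abort(paste0("Invalid structure string for ", label))
  }
  embed_conformers(tibble(id = label, smiles = smiles), seed = seed)[[1]]
}

#' Read a 3D geometry from an SDF/MOL file
#'
#' Coordinates are taken as-is (no re-embedding), so externally minimized
#' structures can be fed straight into the descriptor operators. Requires the
#' ChemmineR package for the V2000 parse.
#'
#' @param path Path to an SDF file; the first record is used.
#' @param embed_seed Integer recorded on the geometry.
#' @return A `qsar_geometry`.
#' @export
read_sdf_geometry <- function(path, embed_seed = NA_integer_) {
  read_sdf_geometries(path, embed_seed = embed_seed)[[1]]
}

#' @rdname read_sdf_geometry
#' @description `read_sdf_geometries()` reads every record of a multi-record
#'   SDF into a named list keyed by the record title.
#' @export
read_sdf_geometries <- function(path, embed_seed = NA_integer_) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("Package ChemmineR is required to read SDF files")
  }
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  titles <- as.character(ChemmineR::sdfid(sdfs))
  out <- lapply(seq_along(sdfs), function(i) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_.*$", "", rownames(ab))
    coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    bonds <- matrix(as.integer(as.matrix(bb[, 1:2, drop = FALSE])), ncol = 2)
    geometry(coords, elements, bonds, embed_seed = embed_seed)
  })
  names(out) <- titles
  out
}

# Rigid-motion helper used by invariance tests and examples.
transform_geometry <- function(g, rotation = diag(3), translation = c(0, 0, 0)) {
  g$coords <- sweep(g$coords %*% t(rotation), 2, -translation)
  g
}
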