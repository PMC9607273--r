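# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# funnel through this so a single integer seed makes them reproducible.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Fan a global seed out to per-stage seeds. Offsets are fixed per stage name
# so each pipeline stage is individually reproducible from the global seed.
.stage_offsets <- c(
  embed = 101L, descriptors = 211L, split = 307L, ga = 401L,
  validation = 503L, scramble = 601L, synthetic = 701L
)

stage_seed <- function(global_seed, stage) {
  stopifnot(stage %in% names(.stage_offsets))
  (as.integer(global_seed) * 1009L + .stage_offsets[[stage]]) %% 2147483629L
}

# A single-row, all-zero descriptor tibble over the given descriptor names.
zero_descriptor_row <- function(descriptor_names, compound_id = "zero") {
  out <- as_tibble(setNames(
    as.list(rep(0, length(descriptor_names))), descriptor_names
  ))
  dplyr::bind_cols(tibble(compound_id = compound_id), out)
}
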