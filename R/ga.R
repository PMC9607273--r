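# Genetic-algorithm descriptor-subset selection for MLR QSAR models.

#' GA-MLR configuration
#'
#' Defaults follow common subset-selection practice at this problem scale:
#' population 50, 200 generations, tournament selection (k = 3), uniform
#' crossover with per-gene probability 0.5, per-gene mutation probability
#' `2 / n_descriptors` (about two flips per chromosome), elitism 1, fitness
#' = leave-one-out \eqn{Q^2} of the candidate subset. Model size defaults to
#' 4 descriptors, the size of both published PON1 models.
#'
#' @param population_size Integer >= 2.
#' @param generations Integer >= 1.
#' @param model_size Descriptors per candidate model.
#' @param crossover_prob Per-gene uniform-crossover probability.
#' @param mutation_prob Per-gene flip probability; `NULL` means
#'   `2 / n_descriptors`, resolved at run time.
#' @param fitness `"Q2LOO"` (default) or `"R2"`.
#' @param tournament_k Tournament size for parent selection.
#' @param elitism Number of best chromosomes copied unchanged each
#'   generation.
#' @param seed Integer RNG seed; the whole search is deterministic given it.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, generations = 200L,
                      model_size = 4L, crossover_prob = 0.5,
                      mutation_prob = NULL, fitness = c("Q2LOO", "R2"),
                      tournament_k = 3L, elitism = 1L, seed = 1L) {
  fitness <- match.arg(fitness)
  if (population_size < 2) abort("`population_size` must be >= 2")
  if (generations < 1) abort("`generations` must be >= 1")
  if (model_size < 1) abort("`model_size` must be >= 1")
  structure(list(
    population_size = as.integer(population_size),
    generations = as.integer(generations),
    model_size = as.integer(model_size),
    crossover_prob = crossover_prob, mutation_prob = mutation_prob,
    fitness = fitness, tournament_k = as.integer(tournament_k),
    elitism = as.integer(elitism), seed = as.integer(seed)
  ), class = "ga_config")
}

# Closed-form LOO Q^2 (and R^2) for one candidate subset. Returns -Inf for
# rank-deficient or leverage-degenerate subsets so they lose any tournament.
subset_fitness <- function(m, y, idx, sstot, what) {
  Xi <- cbind(1, m[, idx, drop = FALSE])
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) return(-Inf)
  e <- qr.resid(qrX, y)
  if (what == "R2") return(1 - sum(e^2) / sstot)
  h <- rowSums(qr.Q(qrX)^2)
  if (any(h > 1 - 1e-10)) return(-Inf)
  1 - sum((e / (1 - h))^2) / sstot
}

#' GA-MLR descriptor-subset search
#'
#' Searches fixed-size descriptor subsets with a genetic algorithm:
#' chromosomes are binary inclusion masks repaired to exactly
#' `config$model_size` ones, parents are chosen by tournament, offspring by
#' uniform crossover and per-gene mutation, and each candidate subset is
#' scored by its cross-validated (or training) fit. Fitness evaluations are
#' memoized per subset. The search is deterministic given `config$seed`.
#'
#' @param x Descriptor tibble (`compound_id` + numeric columns) or numeric
#'   matrix — training rows only.
#' @param y Training responses.
#' After the generational loop, the best distinct subsets are refined by
#' steepest-ascent single-column swaps until locally optimal (each refinement
#' move replaces one selected descriptor by the best available alternative),
#' which protects the search against premature convergence on flat fitness
#' landscapes; set `refine_top = 0` to disable.
#'
#' @param config A [ga_config()].
#' @param n_keep Number of top models to return (default 10).
#' @param refine_top Number of top subsets to hill-climb after the GA loop
#'   (default 5).
#' @return A list of class `qsar_ga`: `models` (list of fitted `qsar_mlr`,
#'   best first), `fitness` (tibble of descriptor sets and scores, ranked),
#'   `config`, and `n_evaluated` (count of distinct subsets scored).
#' @export
ga_select <- function(x, y, config = ga_config(), n_keep = 10L,
                      refine_top = 5L) {
  m <- design_matrix(x)
  n <- nrow(m); ncols <- ncol(m); k <- config$model_size
  if (ncols <= k) {
    abort(paste0("Need more descriptor columns (", ncols,
                 ") than the model size (", k, ")"))
  }
  if (k >= n - 1) abort("`model_size` must be below n_train - 1")
  if (length(y) != n) abort("`y` must match the rows of `x`")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) abort("Zero response variance")
  pmut <- config$mutation_prob %||% (2 / ncols)

  memo <- new.env(parent = emptyenv())
  score <- function(idx) {
    key <- paste(idx, collapse = ",")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- subset_fitness(m, y, idx, sstot, config$fitness)
    memo[[key]] <- val
    val
  }
  repair <- function(mask) {
    ones <- which(mask)
    excess <- length(ones) - k
    if (excess > 0) {
      mask[sample(ones, excess)] <- FALSE
    } else if (excess < 0) {
      mask[sample(which(!mask), -excess)] <- TRUE
    }
    mask
  }

  # Univariate |correlation| with the response guides initialization: the
  # first chromosome is the top-k ranked columns and a handful more are
  # sampled proportionally to |r|, the rest uniformly at random.
  r_abs <- abs(suppressWarnings(as.numeric(stats::cor(m, y))))
  r_abs[!is.finite(r_abs)] <- 0

  result <- with_seed(config$seed, {
    pop <- lapply(seq_len(config$population_size), function(i) {
      sort(sample.int(ncols, k))
    })
    pop[[1]] <- sort(order(-r_abs)[seq_len(k)])
    for (i in seq_len(min(4L, config$population_size - 1L))) {
      pop[[i + 1L]] <- sort(sample.int(ncols, k, prob = r_abs + 1e-6))
    }
    fit <- vapply(pop, score, numeric(1))
    for (gen in seq_len(config$generations)) {
      ord <- order(-fit)
      newpop <- pop[ord[seq_len(min(config$elitism, length(pop)))]]
      while (length(newpop) < config$population_size) {
        pick <- function() {
          cand <- sample.int(length(pop), min(config$tournament_k, length(pop)))
          pop[[cand[which.max(fit[cand])]]]
        }
        pa <- pick(); pb <- pick()
        ma <- seq_len(ncols) %in% pa
        mb <- seq_len(ncols) %in% pb
        swap <- stats::runif(ncols) < config$crossover_prob
        child <- ifelse(swap, mb, ma)
        flip <- stats::runif(ncols) < pmut
        child <- xor(child, flip)
        child <- repair(child)
        newpop[[length(newpop) + 1L]] <- sort(which(child))
      }
      pop <- newpop
      fit <- vapply(pop, score, numeric(1))
    }
    # Memetic refinement: steepest-ascent single-swap hill-climbing from the
    # best subsets seen, until each is locally optimal. Deterministic.
    if (refine_top > 0) {
      keys <- ls(memo)
      scores <- vapply(keys, function(kk) memo[[kk]], numeric(1))
      starts <- lapply(strsplit(keys[head(order(-scores), refine_top)], ","),
                       as.integer)
      for (idx in starts) {
        repeat {
          cur <- score(idx)
          best_val <- cur; best_idx <- idx
          for (pos in seq_along(idx)) {
            for (repl in setdiff(seq_len(ncols), idx)) {
              cand <- sort(c(idx[-pos], repl))
              val <- score(cand)
              if (val > best_val) { best_val <- val; best_idx <- cand }
            }
          }
          if (best_val <= cur + 1e-12) break
          idx <- best_idx
        }
      }
    }
    keys <- ls(memo)
    scores <- vapply(keys, function(kk) memo[[kk]], numeric(1))
    ord <- order(-scores)
    keep <- head(ord, n_keep)
    list(keys = keys[keep], scores = scores[keep])
  })

  sets <- lapply(strsplit(result$keys, ","), as.integer)
  descr <- lapply(sets, function(ix) colnames(m)[ix])
  models <- lapply(descr, function(d) {
    mod <- fit_mlr(as.data.frame(m), y, descriptors = d)
    mod$fit_seed <- config$seed
    mod
  })
  structure(list(
    models = models,
    fitness = tibble(
      rank = seq_along(descr),
      descriptors = vapply(descr, paste, character(1), collapse = "+"),
      fitness = result$scores
    ),
    config = config,
    n_evaluated = length(ls(memo))
  ), class = "qsar_ga")
}

#' @export
print.qsar_ga <- function(x, ...) {
  cat(sprintf("<qsar_ga> %d distinct subsets scored (fitness = %s)\n",
              x$n_evaluated, x$config$fitness))
  print(head(x$fitness, 5))
  invisible(x)
}

#' @describeIn ga_select Ranked subset table (rank, descriptors, fitness).
#' @param x A `qsar_ga`.
#' @param ... Unused.
#' @method tidy qsar_ga
#' @export
tidy.qsar_ga <- function(x, ...) x$fitness
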