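# Compact evolutionary search over 0-1 aligning matrices. The population is
# summarized by one or more probability matrices (PMs) of Bernoulli
# parameters; each generation samples candidate matrices from every PM,
# recombines them, lets the winner of a competition with the PM's elite pull
# the PM toward itself by a small step, and adaptively maintains the PM set
# (removing overlapping PMs, spawning a new one after prolonged stagnation).

#' Engine configuration
#'
#' Collects the tunable parameters of the adaptive compact evolutionary
#' aligner. Defaults: 3000 generations, probability step length 0.01,
#' stagnation threshold `delta = 60` generations and 2 initial probability
#' matrices.
#'
#' @param max_gen maximum number of generations (>= 0).
#' @param step probability-matrix learning step in `(0, 1)`.
#' @param delta stagnation threshold: a new probability matrix is synthesized
#'   after `delta` consecutive generations without any elite replacement.
#' @param pm_num_init initial number of probability matrices (>= 1).
#' @param pa_threshold,na_threshold positive/negative anchor confidence
#'   thresholds (see [detect_anchors()]).
#' @param seed integer seed; every random draw of a run derives from it.
#' @param cardinality `"1:1"` (enforce single cardinality on every sampled
#'   individual) or `"unconstrained"`.
#' @param radius hierarchy radius defining neighbor correspondences for
#'   negative-anchor decay.
#' @param use_mask apply contradiction pruning against positive anchors.
#' @param use_na_decay apply negative-anchor probability decay.
#' @param adaptive maintain the PM set adaptively (overlap removal and
#'   stagnation-triggered synthesis). Setting `pm_num_init = 1`,
#'   `use_mask = FALSE`, `use_na_decay = FALSE`, `adaptive = FALSE` reduces
#'   the engine to the plain compact EA baseline (see [cea_config()]).
#' @param overlap_mode how [pm_distance()] is computed when comparing PMs:
#'   `"mean"` (mean absolute element difference, default) or `"sum"`
#'   (plain sum).
#' @param overlap_threshold distance below which two PMs are considered
#'   redundant. Default: `0.5 / (|O1| * |O2|)` in mean mode (the sum-mode
#'   equivalent of 0.5), or 0.5 in sum mode.
#' @return list of class `acea_config`.
#' @export
acea_config <- function(max_gen = 3000L, step = 0.01, delta = 60L,
                        pm_num_init = 2L, pa_threshold = 0.95,
                        na_threshold = 0.2, seed = 42L,
                        cardinality = c("1:1", "unconstrained"),
                        radius = 1L, use_mask = TRUE, use_na_decay = TRUE,
                        adaptive = TRUE,
                        overlap_mode = c("mean", "sum"),
                        overlap_threshold = NULL) {
  cardinality <- match.arg(cardinality)
  overlap_mode <- match.arg(overlap_mode)
  if (!is_scalar_number(step) || step <= 0 || step >= 1) {
    stop("`step` must lie in (0, 1)", call. = FALSE)
  }
  if (!is_scalar_number(delta) || delta < 1) {
    stop("`delta` must be >= 1", call. = FALSE)
  }
  if (!is_scalar_number(pm_num_init) || pm_num_init < 1) {
    stop("`pm_num_init` must be >= 1", call. = FALSE)
  }
  if (!is_scalar_number(max_gen) || max_gen < 0) {
    stop("`max_gen` must be >= 0", call. = FALSE)
  }
  structure(
    list(max_gen = as.integer(max_gen), step = step,
         delta = as.integer(delta), pm_num_init = as.integer(pm_num_init),
         pa_threshold = pa_threshold, na_threshold = na_threshold,
         seed = as.integer(seed), cardinality = cardinality,
         radius = as.integer(radius), use_mask = isTRUE(use_mask),
         use_na_decay = isTRUE(use_na_decay), adaptive = isTRUE(adaptive),
         overlap_mode = overlap_mode, overlap_threshold = overlap_threshold),
    class = "acea_config"
  )
}

#' Baseline compact-EA configuration
#'
#' The reduction of the engine to a plain compact evolutionary algorithm:
#' one probability matrix, no contradiction mask, no negative-anchor decay
#' and no adaptive PM maintenance. Used as the comparison baseline in
#' benchmarks.
#'
#' @param ... overrides passed to [acea_config()].
#' @return list of class `acea_config`.
#' @export
cea_config <- function(...) {
  args <- list(...)
  base <- list(pm_num_init = 1L, use_mask = FALSE, use_na_decay = FALSE,
               adaptive = FALSE)
  do.call(acea_config, utils::modifyList(base, args))
}

#' Sample an aligning matrix from a probability matrix
#'
#' Independent cell-wise Bernoulli draws: cell `(i, j)` becomes 1 when a
#' uniform draw falls below the probability `P[i, j]`. Draws are consumed in
#' row-major order, so results are reproducible given the RNG state.
#'
#' @param P numeric matrix of probabilities in `[0, 1]`.
#' @return 0-1 matrix of the same shape (and dimnames).
#' @export
sample_am <- function(P) {
  u <- matrix(stats::runif(length(P)), nrow = nrow(P), byrow = TRUE)
  out <- (u < P) * 1
  dimnames(out) <- dimnames(P)
  out
}

#' Uniform crossover of two aligning matrices
#'
#' Each cell is taken from `am2` with probability 0.5 and from `am1`
#' otherwise (draws in row-major order).
#'
#' @param am1,am2 0-1 matrices of identical shape.
#' @return 0-1 matrix of the same shape.
#' @export
uniform_crossover <- function(am1, am2) {
  if (!identical(dim(am1), dim(am2))) {
    stop("crossover operands must have the same shape", call. = FALSE)
  }
  u <- matrix(stats::runif(length(am1)), nrow = nrow(am1), byrow = TRUE)
  out <- ifelse(u < 0.5, am2, am1)
  dimnames(out) <- dimnames(am1)
  out
}

#' Fitness competition between two individuals
#'
#' Returns the matrix with the higher fitness; on a tie the incumbent (the
#' second argument) wins, so an elite is only replaced by a strictly better
#' challenger.
#'
#' @param am_a challenger 0-1 matrix.
#' @param am_b incumbent 0-1 matrix.
#' @param fitness_fn function mapping a matrix to a numeric fitness.
#' @return the winning matrix.
#' @export
compete <- function(am_a, am_b, fitness_fn) {
  if (fitness_fn(am_a) > fitness_fn(am_b)) am_a else am_b
}

#' Move a probability matrix toward an elite individual
#'
#' Adds `step` to every cell where the elite has a 1 and subtracts `step`
#' where it has a 0, clamping to `[0, 1]`. Cells forbidden by the mask are
#' pinned at 0.
#'
#' @param P probability matrix.
#' @param am_elite elite 0-1 matrix of the same shape.
#' @param step learning step in `(0, 1)`.
#' @param mask optional 0-1 contradiction mask.
#' @return updated probability matrix.
#' @export
update_pm_toward_elite <- function(P, am_elite, step, mask = NULL) {
  if (!identical(dim(P), dim(am_elite))) {
    stop("`P` and `am_elite` must have the same shape", call. = FALSE)
  }
  out <- clamp01(P + step * (2 * am_elite - 1))
  if (!is.null(mask)) out <- out * mask
  out
}

#' Distance between two probability matrices
#'
#' Sum (or mean) of absolute element-wise differences, used to detect
#' probability matrices that explore overlapping regions.
#'
#' @param pm_a,pm_b probability matrices of identical shape.
#' @param mode `"sum"` or `"mean"`.
#' @return non-negative number.
#' @export
pm_distance <- function(pm_a, pm_b, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (!identical(dim(pm_a), dim(pm_b))) {
    stop("`pm_a` and `pm_b` must have the same shape", call. = FALSE)
  }
  d <- sum(abs(pm_a - pm_b))
  if (mode == "mean") d <- d / length(pm_a)
  d
}

#' Negative-anchor probability decay
#'
#' Scans the elite's correspondences for negative anchors (confidence below
#' `na_threshold`). Each negative anchor's own probability cell is zeroed,
#' and every neighbor correspondence within hierarchy `radius` that does not
#' logically contradict the anchor has its probability reduced by `step`
#' (clamped at 0): a very poor mapping casts doubt on the mappings of the
#' concepts around it, except those the anchor already rules out by
#' contradiction.
#'
#' @param P probability matrix.
#' @param am_elite elite 0-1 matrix.
#' @param sims similarity/confidence matrix.
#' @param na_threshold negative-anchor threshold.
#' @param step decay step.
#' @param o1,o2 the aligned ontologies.
#' @param radius neighborhood radius (default 1).
#' @param ctx optional precomputed reasoning context (internal use).
#' @return updated probability matrix.
#' @export
apply_na_decay <- function(P, am_elite, sims, na_threshold, step, o1, o2,
                           radius = 1L, ctx = NULL) {
  if (is.null(ctx)) ctx <- reasoning_context(o1, o2, radius)
  ones <- which(am_elite == 1 & sims < na_threshold, arr.ind = TRUE)
  if (!nrow(ones)) return(P)
  for (k in seq_len(nrow(ones))) {
    i <- ones[k, 1]
    j <- ones[k, 2]
    P[i, j] <- 0
    for (m in ctx$nbr1[[i]]) {
      for (n in ctx$nbr2[[j]]) {
        if (m == i && n == j) next
        contradicting <-
          (ctx$anc1[i, m] && ctx$anc2[n, j]) ||
          (ctx$anc1[m, i] && ctx$anc2[j, n])
        if (!contradicting) {
          P[m, n] <- max(0, P[m, n] - step)
        }
      }
    }
  }
  P
}

# Precomputed reachability and neighborhoods, by entity index.
reasoning_context <- function(o1, o2, radius = 1L) {
  idx_list <- function(o) {
    ids <- o$entities$id
    lapply(neighborhood_list(o, radius), function(nb) {
      match(nb, ids)
    })
  }
  list(
    anc1 = ancestor_matrix(o1), anc2 = ancestor_matrix(o2),
    nbr1 = idx_list(o1), nbr2 = idx_list(o2)
  )
}

#' Initialize a probability matrix and its elite individual
#'
#' A fresh probability matrix has all admissible cells at 0.5 (maximum
#' uncertainty, which also spreads the sampled 1-cells evenly) and all
#' mask-forbidden cells at 0. The elite is sampled cell-wise from the matrix,
#' masked, and repaired to single cardinality when configured.
#'
#' @param P optional existing probability matrix (e.g. from
#'   [synthesize_new_pm()]); when `NULL` a uniform 0.5 matrix is created.
#' @param mask 0-1 contradiction mask (defines the shape).
#' @param sims similarity matrix (confidence lookup for repair/fitness).
#' @param fitness_fn function mapping a 0-1 matrix to its fitness.
#' @param cardinality `"1:1"` or `"unconstrained"`.
#' @return list with `P`, `elite` and `elite_fit`.
#' @export
initialize_pm_and_elite <- function(P = NULL, mask, sims, fitness_fn,
                                    cardinality = "1:1") {
  if (is.null(P)) {
    P <- matrix(0.5, nrow(mask), ncol(mask), dimnames = dimnames(mask))
  }
  if (!identical(dim(P), dim(mask))) {
    stop("probability matrix shape does not match the mask", call. = FALSE)
  }
  P <- P * mask
  elite <- sample_am(P) * mask
  if (cardinality == "1:1") elite <- enforce_single_cardinality(elite, sims)
  list(P = P, elite = elite, elite_fit = fitness_fn(elite))
}

#' Synthesize a probability matrix pointing away from the current ones
#'
#' Builds a new probability matrix from the cell-wise maximum `m` and minimum
#' `n` over the existing matrices: cells on which all matrices agree at 0 or
#' 1 are kept; where even the largest probability is below 0.5 the new cell is
#' pushed right of it (`m + u (1 - m)`, `u ~ U(0, 1)`); where even the
#' smallest is above 0.5 it is pushed left (`(1 - u) n`); where the matrices
#' straddle 0.5 the new cell sits at 0.5. The result explores regions the
#' current matrices have written off.
#'
#' @param existing non-empty list of probability matrices.
#' @param mask optional 0-1 contradiction mask (forbidden cells stay 0).
#' @return new probability matrix.
#' @export
synthesize_new_pm <- function(existing, mask = NULL) {
  stopifnot(length(existing) >= 1L)
  m <- Reduce(pmax, existing)
  n <- Reduce(pmin, existing)
  u <- matrix(stats::runif(length(m)), nrow = nrow(m), byrow = TRUE)
  new <- matrix(0.5, nrow(m), ncol(m), dimnames = dimnames(m))
  agree1 <- (m == 1) & (n == 1)
  agree0 <- (m == 0) & (n == 0)
  low <- !agree0 & !agree1 & (m < 0.5)
  high <- !agree0 & !agree1 & (n > 0.5)
  new[agree1] <- 1
  new[agree0] <- 0
  new[low] <- m[low] + u[low] * (1 - m[low])
  new[high] <- (1 - u[high]) * n[high]
  # remaining cells (m >= 0.5 >= n, not unanimous) stay at 0.5
  new <- clamp01(new)
  if (!is.null(mask)) new <- new * mask
  new
}

# fitness of a (masked, repaired) aligning matrix, memoized by 1-cell pattern
make_fitness_fn <- function(sims, n1, n2) {
  min_size <- min(n1, n2)
  cache <- new.env(parent = emptyenv())
  function(M) {
    ones <- which(M == 1)
    key <- paste(ones, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    size <- length(ones)
    f <- if (size == 0L || min_size == 0L) {
      0
    } else {
      r <- min(1, size / min_size)
      p <- sum(sims[ones]) / size
      if (p + r == 0) 0 else 2 * p * r / (p + r)
    }
    if (length(cache) < 20000L) cache[[key]] <- f
    f
  }
}

#' Initialize the engine state
#'
#' Computes (or accepts) the similarity matrix, detects positive anchors,
#' builds the contradiction mask, and initializes `pm_num_init` probability
#' matrices with their elites. Randomness is governed by `config$seed` when
#' `seeded = TRUE` (the default inside [acea_run()] is to seed once for the
#' whole run).
#'
#' @param o1,o2 source/target [ontology][new_ontology] objects.
#' @param sims optional precomputed similarity matrix (from
#'   [similarity_matrix()]).
#' @param config an [acea_config()].
#' @param thesaurus thesaurus used when `sims` must be computed.
#' @return list of class `acea_state`.
#' @export
acea_init <- function(o1, o2, sims = NULL, config = acea_config(),
                      thesaurus = acealign::thesaurus()) {
  if (is.null(sims)) sims <- similarity_matrix(o1, o2, t = thesaurus)
  n1 <- ontology_size(o1)
  n2 <- ontology_size(o2)
  stopifnot(identical(dim(sims), c(n1, n2)))

  anchors <- if (n1 && n2) {
    detect_anchors(sims, config$pa_threshold, config$na_threshold)
  } else {
    NULL
  }
  mask <- if (config$use_mask && !is.null(anchors)) {
    prune_mask(o1, o2, anchors$positive)
  } else {
    matrix(1, n1, n2, dimnames = list(o1$entities$id, o2$entities$id))
  }
  ctx <- if (config$use_na_decay) reasoning_context(o1, o2, config$radius)
  fitness_fn <- make_fitness_fn(sims, n1, n2)

  pms <- lapply(seq_len(config$pm_num_init), function(k) {
    initialize_pm_and_elite(NULL, mask, sims, fitness_fn, config$cardinality)
  })
  fits <- vapply(pms, `[[`, numeric(1), "elite_fit")
  best_k <- which.max(fits)
  state <- list(
    o1 = o1, o2 = o2, sims = sims, mask = mask, ctx = ctx,
    fitness_fn = fitness_fn, config = config, pms = pms, gen = 0L,
    stagnation = 0L,
    best = list(am = pms[[best_k]]$elite, fitness = fits[best_k]),
    trace = data.frame(generation = 0L, pm_count = length(pms),
                       best_fitness = fits[best_k])
  )
  class(state) <- "acea_state"
  state
}

#' Advance the engine by one generation
#'
#' For every probability matrix: sample two individuals, recombine them with
#' uniform crossover, mask and repair the offspring, let it compete with the
#' PM's elite, pull the PM toward the (possibly new) elite, and apply
#' negative-anchor decay. Afterwards the PM set is maintained adaptively (see
#' [maintain_pms()]) and the trace is extended.
#'
#' @param state an `acea_state` from [acea_init()].
#' @return the updated state.
#' @export
acea_step <- function(state) {
  cfg <- state$config
  changed <- FALSE
  for (k in seq_along(state$pms)) {
    pm <- state$pms[[k]]
    am1 <- sample_am(pm$P)
    am2 <- sample_am(pm$P)
    am_new <- uniform_crossover(am1, am2)
    am_new <- am_new * state$mask
    if (cfg$cardinality == "1:1") {
      am_new <- enforce_single_cardinality(am_new, state$sims)
    }
    f_new <- state$fitness_fn(am_new)
    if (f_new > pm$elite_fit) {
      pm$elite <- am_new
      pm$elite_fit <- f_new
      changed <- TRUE
      if (f_new > state$best$fitness) {
        state$best <- list(am = am_new, fitness = f_new)
      }
    }
    pm$P <- update_pm_toward_elite(pm$P, pm$elite, cfg$step, state$mask)
    if (cfg$use_na_decay) {
      pm$P <- apply_na_decay(pm$P, pm$elite, state$sims, cfg$na_threshold,
                             cfg$step, state$o1, state$o2, cfg$radius,
                             ctx = state$ctx)
    }
    state$pms[[k]] <- pm
  }
  state$stagnation <- if (changed) 0L else state$stagnation + 1L
  if (cfg$adaptive) state <- maintain_pms(state)
  state$gen <- state$gen + 1L
  state$trace <- rbind(state$trace, data.frame(
    generation = state$gen, pm_count = length(state$pms),
    best_fitness = state$best$fitness
  ))
  state
}

#' Adaptive maintenance of the probability-matrix set
#'
#' Two mechanisms adjust the search directions: (1) when two probability
#' matrices are closer than the overlap threshold they explore the same
#' region, so the one with the worse elite is removed (the set never drops
#' below one matrix); (2) when no elite has changed for `delta` consecutive
#' generations the search is stuck, so a new probability matrix pointing away
#' from the existing ones is synthesized ([synthesize_new_pm()]), given a
#' fresh elite, and appended; the stagnation counter then resets.
#'
#' @param state an `acea_state`.
#' @return the updated state.
#' @export
maintain_pms <- function(state) {
  cfg <- state$config
  threshold <- cfg$overlap_threshold
  if (is.null(threshold)) {
    threshold <- if (cfg$overlap_mode == "mean") {
      0.5 / max(1, length(state$mask))
    } else {
      0.5
    }
  }
  # overlap removal (never below one PM)
  k <- 1L
  while (k < length(state$pms)) {
    j <- k + 1L
    removed <- FALSE
    while (j <= length(state$pms)) {
      d <- pm_distance(state$pms[[k]]$P, state$pms[[j]]$P, cfg$overlap_mode)
      if (d < threshold && length(state$pms) > 1L) {
        drop <- if (state$pms[[k]]$elite_fit >= state$pms[[j]]$elite_fit) j else k
        state$pms[[drop]] <- NULL
        if (drop == k) { removed <- TRUE; break }
      } else {
        j <- j + 1L
      }
    }
    if (!removed) k <- k + 1L
  }
  # stagnation-triggered synthesis
  if (state$stagnation >= cfg$delta) {
    P_new <- synthesize_new_pm(lapply(state$pms, `[[`, "P"), state$mask)
    pm_new <- initialize_pm_and_elite(P_new, state$mask, state$sims,
                                      state$fitness_fn, cfg$cardinality)
    state$pms[[length(state$pms) + 1L]] <- pm_new
    if (pm_new$elite_fit > state$best$fitness) {
      state$best <- list(am = pm_new$elite, fitness = pm_new$elite_fit)
    }
    state$stagnation <- 0L
  }
  state
}

#' Align two ontologies with the adaptive compact evolutionary engine
#'
#' Runs the full search: anchor detection and contradiction pruning,
#' compact evolution of `pm_num_init` probability matrices for `max_gen`
#' generations with adaptive PM maintenance, and extraction of the best
#' elite's alignment. The run is fully deterministic given `config$seed`.
#'
#' @inheritParams acea_init
#' @return list with `alignment` (an [alignment][new_alignment]), `fitness`
#'   (its approximated f-measure), `trace` (data frame
#'   `generation, pm_count, best_fitness`) and `state` (final engine state).
#' @export
#' @examples
#' fx <- generate_fixture_pair(fixture_spec(n_concepts = 10, seed = 7))
#' res <- acea_run(fx$o1, fx$o2, config = acea_config(max_gen = 50, seed = 1),
#'                 thesaurus = fixture_thesaurus())
#' evaluate_against_reference(res$alignment, fx$reference)
acea_run <- function(o1, o2, sims = NULL, config = acea_config(),
                     thesaurus = acealign::thesaurus()) {
  if (ontology_size(o1) == 0L || ontology_size(o2) == 0L) {
    warning("empty ontology: returning the empty alignment")
    empty <- new_alignment(source = o1$name, target = o2$name)
    return(list(alignment = empty, fitness = 0,
                trace = data.frame(generation = 0L, pm_count = 0L,
                                   best_fitness = 0),
                state = NULL))
  }
  if (is.null(sims)) sims <- similarity_matrix(o1, o2, t = thesaurus)
  with_local_seed(config$seed, {
    state <- acea_init(o1, o2, sims, config, thesaurus)
    gen <- 0L
    while (gen < config$max_gen) {
      state <- acea_step(state)
      gen <- gen + 1L
    }
    A <- matrix_to_alignment(state$best$am, state$sims,
                             source = o1$name, target = o2$name)
    list(alignment = A, fitness = state$best$fitness, trace = state$trace,
         state = state)
  })
}
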