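#' Search budgets
#'
#' Bounds a lattice search by wall-clock time and/or by the number of
#' (unique) scheme evaluations. Budgets are checked between evaluations; a
#' single evaluation is never interrupted. Evaluation caps make runs
#' hardware-independent and exactly reproducible.
#'
#' @param time_limit seconds, or `NULL` for no time bound.
#' @param max_evaluations integer cap on unique scheme evaluations, or
#'   `NULL`.
#' @export
search_budget <- function(time_limit = NULL, max_evaluations = NULL) {
  if (!is.null(time_limit) && time_limit <= 0) stop("time_limit must be > 0")
  if (!is.null(max_evaluations) && max_evaluations < 1)
    stop("max_evaluations must be >= 1")
  structure(list(time_limit = time_limit,
                 max_evaluations = if (is.null(max_evaluations)) NULL
                                   else as.integer(max_evaluations)),
            class = "search_budget")
}

# Mutable per-run search state: memo of evaluated schemes, incumbent best,
# trace, budget clock.
new_search_state <- function(ctx, budget = NULL) {
  e <- new.env(parent = emptyenv())
  e$ctx <- ctx
  e$budget <- budget %||% search_budget()
  e$memo <- new.env(parent = emptyenv())
  e$evaluations <- 0L
  e$start <- proc.time()[["elapsed"]]
  e$best_quality <- -Inf
  e$best_scheme <- NULL
  e$trace <- list()
  e
}

budget_exhausted <- function(st) {
  b <- st$budget
  (!is.null(b$max_evaluations) && st$evaluations >= b$max_evaluations) ||
    (!is.null(b$time_limit) &&
       proc.time()[["elapsed"]] - st$start >= b$time_limit)
}

# Fast fitness of one scheme: recode via precomputed level codes, suppress to
# satisfy the context's privacy model, score granularity. Memoized per run.
# Incumbent ties go to the lexicographically smallest level vector.
eval_scheme_fast <- function(st, g) {
  key <- scheme_key(g)
  hit <- st$memo[[key]]
  if (!is.null(hit)) return(hit)
  ctx <- st$ctx
  ids <- class_ids(ctx, g)
  sizes <- tabulate(ids)
  suppressed <- suppressed_records(ctx, g, ids, sizes)
  quality <- granularity_fast(ctx, g, suppressed)
  res <- list(quality = quality, n_suppressed = sum(suppressed),
              sizes = sizes[tabulate(ids[!suppressed],
                                     nbins = length(sizes)) > 0L],
              suppressed = suppressed, scheme = g)
  st$memo[[key]] <- res
  st$evaluations <- st$evaluations + 1L
  if (quality > st$best_quality ||
      (quality == st$best_quality && scheme_lex_lt(g, st$best_scheme))) {
    st$best_quality <- quality
    st$best_scheme <- g
    st$trace[[length(st$trace) + 1L]] <-
      list(elapsed = proc.time()[["elapsed"]] - st$start,
           evaluations = st$evaluations, quality = quality, scheme = g)
  }
  res
}

# Logical vector: records suppressed to satisfy the context's privacy model
# under the class partition given by ids/sizes.
suppressed_records <- function(ctx, g, ids, sizes) {
  model <- ctx$privacy
  if (ctx$n == 0L) return(logical(0))
  if (inherits(model, "k_anonymity"))
    return(sizes[ids] < model$k)
  if (inherits(model, "population_uniqueness")) {
    first_seen <- match(seq_along(sizes), ids)
    ord <- order(sizes, first_seen)
    alive <- rep(TRUE, length(sizes))
    i <- 1L
    while (any(alive)) {
      est <- estimate_population_uniqueness(sizes[alive],
                                            model$sampling_fraction)
      if (est <= model$threshold) break
      alive[ord[i]] <- FALSE
      i <- i + 1L
    }
    return(!alive[ids])
  }
  stop("unknown privacy model of class ", paste(class(model), collapse = "/"))
}

granularity_fast <- function(ctx, g, suppressed) {
  m <- length(ctx$qi)
  if (ctx$n == 0L || m == 0L) return(100)
  keep <- !suppressed
  total <- sum(!keep) * m
  for (i in seq_len(m))
    total <- total + sum(ctx$attrs[[i]]$loss[keep, g[i] + 1L])
  100 * (1 - total / (ctx$n * m))
}

#' Evaluate one generalization scheme
#'
#' Applies the scheme, suppresses records until the context's privacy model
#' holds, and scores the result with the granularity model — the fitness
#' function every search algorithm optimizes.
#'
#' @param ctx an [anon_context()].
#' @param scheme integer level vector.
#' @return List with `quality` (percent), `n_suppressed`, and `sizes`
#'   (post-suppression class histogram).
#' @export
evaluate_scheme <- function(ctx, scheme) {
  scheme <- check_scheme(ctx, as.integer(scheme))
  st <- new_search_state(ctx)
  res <- eval_scheme_fast(st, scheme)
  res[c("quality", "n_suppressed", "sizes")]
}

finish_result <- function(st, algorithm, extra = list()) {
  best <- st$memo[[scheme_key(st$best_scheme)]]
  structure(c(list(scheme = st$best_scheme,
                   quality = st$best_quality,
                   n_suppressed = best$n_suppressed,
                   class_sizes = best$sizes,
                   evaluations = st$evaluations,
                   elapsed = proc.time()[["elapsed"]] - st$start,
                   algorithm = algorithm,
                   trace = search_trace(st$trace)),
              extra),
            class = "anon_search_result")
}

search_trace <- function(entries) {
  data.frame(elapsed = vapply(entries, `[[`, numeric(1), "elapsed"),
             evaluations = vapply(entries, `[[`, integer(1), "evaluations"),
             quality = vapply(entries, `[[`, numeric(1), "quality"),
             scheme = vapply(entries, function(e)
               paste(e$scheme, collapse = ","), character(1)))
}

#' @export
print.anon_search_result <- function(x, ...) {
  cat(x$algorithm, " search: best scheme [",
      paste(x$scheme, collapse = ", "), "] at quality ",
      formatC(x$quality, format = "f", digits = 1), "%\n", sep = "")
  cat("  ", x$n_suppressed, " records suppressed; ", x$evaluations,
      " schemes evaluated in ", formatC(x$elapsed, format = "f", digits = 2),
      " s\n", sep = "")
  invisible(x)
}

#' Exhaustive lattice search
#'
#' Evaluates every generalization scheme of the lattice and returns the
#' maximum-quality one (ties broken by the lexicographically smallest level
#' vector). The oracle against which the heuristics are judged; only
#' tractable for small lattices, so it refuses to enumerate more schemes
#' than `cap`.
#'
#' @param ctx an [anon_context()].
#' @param cap maximum lattice size to enumerate (default 100000).
#' @return An `"anon_search_result"`.
#' @export
search_exhaustive <- function(ctx, cap = 1e5) {
  size <- lattice_size(ctx$heights)
  if (is.character(size) || size > cap)
    stop("lattice has ", size, " schemes, above the exhaustive cap of ", cap,
         "; use a heuristic search (bottom_up, top_down, genetic)")
  st <- new_search_state(ctx)
  schemes <- enumerate_schemes(ctx$heights)
  for (r in seq_len(nrow(schemes))) eval_scheme_fast(st, schemes[r, ])
  finish_result(st, "exhaustive")
}

#' Greedy best-first lattice search
#'
#' Starts at the bottom scheme (no generalization; `direction = "bottom_up"`)
#' or at the top (everything generalized to the root; `"top_down"`) and
#' repeatedly expands the best-quality scheme evaluated so far that has not
#' yet been expanded, evaluating all its up- (resp. down-) neighbours. Ties
#' are broken by the lexicographically smallest level vector. The search
#' stops when the budget is exhausted or no unexpanded scheme remains — in
#' the latter case the whole lattice has been evaluated and the result equals
#' the exhaustive optimum.
#'
#' @param ctx an [anon_context()].
#' @param direction `"bottom_up"` or `"top_down"`.
#' @param budget a [search_budget()]; `NULL` means run to exhaustion.
#' @return An `"anon_search_result"`.
#' @export
search_greedy <- function(ctx, direction = c("bottom_up", "top_down"),
                          budget = NULL) {
  direction <- match.arg(direction)
  st <- new_search_state(ctx, budget)
  nbr_dir <- if (direction == "bottom_up") "up" else "down"
  start <- if (direction == "bottom_up") rep(0L, length(ctx$heights))
           else ctx$heights
  open <- list()   # evaluated but not yet expanded
  add_open <- function(g, q) open[[scheme_key(g)]] <<- list(g = g, q = q)
  r <- eval_scheme_fast(st, start)
  add_open(start, r$quality)
  while (length(open) > 0L && !budget_exhausted(st)) {
    # best-quality unexpanded scheme, lexicographic tie-break
    best_i <- 1L
    for (i in seq_along(open)) {
      if (open[[i]]$q > open[[best_i]]$q ||
          (open[[i]]$q == open[[best_i]]$q &&
           scheme_lex_lt(open[[i]]$g, open[[best_i]]$g)))
        best_i <- i
    }
    node <- open[[best_i]]
    open[[names(open)[best_i]]] <- NULL
    nbrs <- neighbors(node$g, ctx$heights, nbr_dir)
    for (j in seq_len(nrow(nbrs))) {
      if (budget_exhausted(st)) break
      g <- nbrs[j, ]
      if (is.null(st$memo[[scheme_key(g)]])) {
        rj <- eval_scheme_fast(st, g)
        add_open(g, rj$quality)
      }
    }
  }
  finish_result(st, direction)
}

#' Triangle-pattern initialization for the genetic search
#'
#' Deterministic seed individuals built from the lowest and highest
#' generalization levels: row `j` sets the first `j` genes to their maximum
#' level and the rest to 0, starting from the all-zero scheme. For heights
#' `[3, 1, 5, 3, 1]` this yields `[0,0,0,0,0]`, `[3,0,0,0,0]`, `[3,1,0,0,0]`,
#' ..., `[3,1,5,3,1]`. At most `min(m + 1, count)` schemes are produced.
#'
#' @param heights per-attribute hierarchy heights.
#' @param count number of schemes wanted (>= 1).
#' @return Integer matrix, one scheme per row.
#' @export
triangle_init <- function(heights, count) {
  stopifnot(count >= 1)
  m <- length(heights)
  k <- min(m + 1L, count)
  out <- matrix(0L, nrow = k, ncol = m)
  for (j in seq_len(k) - 1L)
    if (j > 0L) out[j + 1L, seq_len(j)] <- as.integer(heights[seq_len(j)])
  out
}

#' Genetic-algorithm configuration
#'
#' Tuning parameters of the genetic lattice search and their standard
#' defaults: per generation the fittest `elite_fraction` of a subpopulation
#' is copied unchanged, `crossover_fraction` is replaced by children of two
#' parents drawn from the top `production_fraction`, and the remainder are
#' mutants with between 1 and `round(mutation_probability * m)` genes
#' resampled. Every `immigration_interval` iterations the top
#' `immigration_fraction` of each of the two subpopulations replaces the
#' bottom of the other.
#'
#' @param elite_fraction,crossover_fraction,production_fraction fractions of
#'   the subpopulation (defaults 0.2, 0.4, 0.2).
#' @param mutation_probability per-gene factor bounding how many genes a
#'   mutation may change (default 0.05).
#' @param immigration_fraction,immigration_interval swap size (default 0.2)
#'   and period in iterations (default 10).
#' @param iterations number of generations (default 50).
#' @param subpopulation_size individuals per subpopulation (default 50).
#' @export
ga_config <- function(elite_fraction = 0.2, crossover_fraction = 0.4,
                      production_fraction = 0.2, mutation_probability = 0.05,
                      immigration_fraction = 0.2, immigration_interval = 10L,
                      iterations = 50L, subpopulation_size = 50L) {
  fracs <- c(elite_fraction = elite_fraction,
             crossover_fraction = crossover_fraction,
             production_fraction = production_fraction,
             mutation_probability = mutation_probability,
             immigration_fraction = immigration_fraction)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad)) stop("fraction(s) outside [0, 1]: ",
                        paste(bad, collapse = ", "))
  if (elite_fraction + crossover_fraction > 1)
    stop("elite_fraction + crossover_fraction must be <= 1")
  if (subpopulation_size < 2) stop("subpopulation_size must be >= 2")
  if (iterations < 1) stop("iterations must be >= 1")
  if (immigration_interval < 1) stop("immigration_interval must be >= 1")
  structure(list(elite_fraction = elite_fraction,
                 crossover_fraction = crossover_fraction,
                 production_fraction = production_fraction,
                 mutation_probability = mutation_probability,
                 immigration_fraction = immigration_fraction,
                 immigration_interval = as.integer(immigration_interval),
                 iterations = as.integer(iterations),
                 subpopulation_size = as.integer(subpopulation_size)),
            class = "ga_config")
}

round_half_up <- function(x) floor(x + 0.5)

#' Advance one genetic-algorithm generation
#'
#' Sorts a subpopulation by fitness (descending, ties to the
#' lexicographically smallest scheme), then fills the next generation with
#' the elite (copied unchanged), crossover children (each gene inherited from
#' one of two distinct parents drawn from the production fraction with
#' probability proportional to the rank weight `p - rank + 1`), and mutants
#' (uniformly chosen current individuals with 1 to
#' `max(1, round(mutation_probability * m))` genes resampled uniformly over
#' their full level range). Fraction-derived counts use round-half-up with
#' floors of 1 elite and 2 producers.
#'
#' @param pop integer matrix, one individual (scheme) per row.
#' @param fitness numeric vector of fitness values for the rows of `pop`.
#' @param cfg a [ga_config()].
#' @param heights per-attribute hierarchy heights.
#' @return Integer matrix of the next generation (same number of rows).
#'   Consumes the R random number stream.
#' @export
next_generation <- function(pop, fitness, cfg, heights) {
  s <- nrow(pop)
  m <- ncol(pop)
  ord <- do.call(order, c(list(-fitness), as.data.frame(pop)))
  pop <- pop[ord, , drop = FALSE]
  e <- max(1L, round_half_up(cfg$elite_fraction * s))
  cc <- round_half_up(cfg$crossover_fraction * s)
  cc <- min(cc, s - e)
  p <- max(2L, round_half_up(cfg$production_fraction * s))
  p <- min(p, s)
  nxt <- matrix(0L, nrow = s, ncol = m)
  nxt[seq_len(e), ] <- pop[seq_len(e), , drop = FALSE]
  if (cc > 0L) {
    w <- (p:1)
    for (i in seq_len(cc)) {
      parents <- sample.int(p, 2L, replace = FALSE, prob = w)
      pick <- sample.int(2L, m, replace = TRUE)
      nxt[e + i, ] <- ifelse(pick == 1L, pop[parents[1L], ],
                             pop[parents[2L], ])
    }
  }
  n_mut <- s - e - cc
  if (n_mut > 0L) {
    bound <- max(1L, round_half_up(cfg$mutation_probability * m))
    for (i in seq_len(n_mut)) {
      base <- pop[sample.int(s, 1L), ]
      k <- if (bound == 1L) 1L else sample.int(bound, 1L)
      genes <- if (m == 1L) 1L else sample.int(m, k, replace = FALSE)
      for (gidx in genes)
        base[gidx] <- sample.int(heights[gidx] + 1L, 1L) - 1L
      nxt[e + cc + i, ] <- base
    }
  }
  nxt
}

random_schemes <- function(heights, count) {
  m <- length(heights)
  out <- matrix(0L, nrow = count, ncol = m)
  for (j in seq_len(m))
    out[, j] <- sample.int(heights[j] + 1L, count, replace = TRUE) - 1L
  out
}

#' Genetic lattice search
#'
#' Two-subpopulation genetic algorithm over generalization schemes: genes are
#' per-attribute generalization levels and fitness is post-suppression output
#' quality. Subpopulation 1 is seeded with the deterministic
#' [triangle_init()] pattern and filled with uniform-random schemes;
#' subpopulation 2 is fully random. Each iteration advances both
#' subpopulations with [next_generation()]; every `immigration_interval`
#' iterations the fittest `round(immigration_fraction * s)` individuals of
#' each subpopulation replace the weakest of the other (simultaneous
#' exchange, both directions computed from the pre-swap state). The search
#' stops after `cfg$iterations` generations or when the budget runs out and
#' returns the best scheme seen anywhere.
#'
#' @param ctx an [anon_context()].
#' @param cfg a [ga_config()].
#' @param budget optional [search_budget()].
#' @param seed integer seed for the run's random generator (required for
#'   reproducibility).
#' @return An `"anon_search_result"`.
#' @export
search_genetic <- function(ctx, cfg = ga_config(), budget = NULL,
                           seed = 1L) {
  st <- new_search_state(ctx, budget)
  s <- cfg$subpopulation_size
  m <- length(ctx$heights)
  with_preserved_rng(seed, {
    tri <- triangle_init(ctx$heights, s)
    pop1 <- rbind(tri, random_schemes(ctx$heights, s - nrow(tri)))
    pop2 <- random_schemes(ctx$heights, s)
    fit1 <- pop_fitness(st, pop1)
    fit2 <- pop_fitness(st, pop2)
    iter <- 0L
    while (iter < cfg$iterations && !budget_exhausted(st)) {
      iter <- iter + 1L
      pop1 <- next_generation(pop1, fit1, cfg, ctx$heights)
      pop2 <- next_generation(pop2, fit2, cfg, ctx$heights)
      fit1 <- pop_fitness(st, pop1)
      fit2 <- pop_fitness(st, pop2)
      if (iter %% cfg$immigration_interval == 0L) {
        ni <- round_half_up(cfg$immigration_fraction * s)
        if (ni > 0L) {
          o1 <- do.call(order, c(list(-fit1), as.data.frame(pop1)))
          o2 <- do.call(order, c(list(-fit2), as.data.frame(pop2)))
          top1 <- pop1[o1[seq_len(ni)], , drop = FALSE]
          top2 <- pop2[o2[seq_len(ni)], , drop = FALSE]
          pop1[o1[s - ni + seq_len(ni)], ] <- top2
          pop2[o2[s - ni + seq_len(ni)], ] <- top1
          fit1 <- pop_fitness(st, pop1)
          fit2 <- pop_fitness(st, pop2)
        }
      }
    }
  })
  finish_result(st, "genetic", extra = list(seed = seed))
}

# Fitness of every row; memoized evaluations, budget-aware (already-known
# schemes are free; new ones stop being evaluated once the budget is spent,
# keeping their fitness at the worst value so they are never selected).
pop_fitness <- function(st, pop) {
  q <- numeric(nrow(pop))
  for (r in seq_len(nrow(pop))) {
    key <- scheme_key(pop[r, ])
    hit <- st$memo[[key]]
    if (!is.null(hit)) { q[r] <- hit$quality; next }
    if (budget_exhausted(st)) { q[r] <- -Inf; next }
    q[r] <- eval_scheme_fast(st, pop[r, ])$quality
  }
  q
}

# Run code with the RNG seeded to `seed`, restoring the caller's random
# stream afterwards.
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
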