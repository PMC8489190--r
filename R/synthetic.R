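#' Generate synthetic categorical microdata with balanced hierarchies
#'
#' Builds a categorical dataset plus one balanced generalization hierarchy
#' per attribute so every algorithm can be exercised without external data.
#' Leaf values of attribute `j` are zero-padded integer codes
#' (`"a3_007"`-style prefixes keep attributes distinct); hierarchy level `l`
#' groups the codes into blocks of `branching_factor^l` consecutive values,
#' labelled by their code range, and the top level is `"*"`. The height of
#' attribute `j` is therefore `ceiling(log(domain_size, branching_factor))`.
#' Values are drawn uniformly or from a Zipf law with exponent `s`
#' (`P(value = v) ~ 1/v^s`), which yields the mix of common and rare
#' combinations that makes suppression behaviour non-trivial.
#'
#' @param n_records number of records.
#' @param attributes list with one entry per attribute: a list/vector with
#'   `domain_size` (>= 1), `branching_factor` (>= 2, default 2) and
#'   `distribution` (`"uniform"` or `"zipf"`, default `"uniform"`), plus
#'   optional `s` (Zipf exponent, default 1).
#' @param seed integer seed; the same spec and seed reproduce the dataset
#'   bit-identically.
#' @return List with `data` (an [anon_dataset()], all attributes
#'   quasi-identifying) and `hierarchies` (named list of [hierarchy()]
#'   objects).
#' @examples
#' syn <- generate_dataset(100, list(list(domain_size = 8),
#'                                   list(domain_size = 4)), seed = 42)
#' sapply(syn$hierarchies, hierarchy_height)  # 3, 2
#' @export
generate_dataset <- function(n_records, attributes, seed = 1L) {
  stopifnot(n_records >= 0, length(attributes) >= 1)
  cols <- list()
  hiers <- list()
  with_preserved_rng(seed, {
    for (j in seq_along(attributes)) {
      a <- as.list(attributes[[j]])
      D <- as.integer(a$domain_size)
      stopifnot(D >= 1L)
      b <- as.integer(a$branching_factor %||% 2L)
      stopifnot(b >= 2L)
      dist <- a$distribution %||% "uniform"
      name <- a$name %||% paste0("attr", j)
      hiers[[name]] <- balanced_hierarchy(name, D, b)
      prob <- switch(dist,
                     uniform = rep(1 / D, D),
                     zipf = {
                       s <- a$s %||% 1
                       w <- 1 / seq_len(D)^s
                       w / sum(w)
                     },
                     stop("unknown distribution: ", dist))
      draws <- if (n_records > 0)
        sample.int(D, n_records, replace = TRUE, prob = prob) else integer()
      cols[[name]] <- hierarchy_leaves(hiers[[name]])[draws]
    }
  })
  data <- if (n_records > 0) as.data.frame(cols, check.names = FALSE,
                                           stringsAsFactors = FALSE)
          else as.data.frame(lapply(cols, function(x) character()),
                             check.names = FALSE)
  roles <- setNames(rep("quasi_identifying", length(hiers)), names(hiers))
  list(data = anon_dataset(data, roles), hierarchies = hiers)
}

# Balanced hierarchy over D zero-padded codes: level l groups blocks of b^l
# consecutive codes, top level "*".
balanced_hierarchy <- function(name, D, b) {
  L <- if (D <= 1L) 0L else as.integer(ceiling(log(D) / log(b)))
  width <- nchar(as.character(D - 1L))
  code <- formatC(seq_len(D) - 1L, width = width, flag = "0")
  cols <- list(code)
  if (L > 0L) for (l in seq_len(L)) {
    block <- (seq_len(D) - 1L) %/% (b^l)
    if (l == L) {
      cols[[l + 1L]] <- rep("*", D)
    } else {
      lo <- formatC(block * b^l, width = width, flag = "0")
      hi <- formatC(pmin(D - 1L, (block + 1L) * b^l - 1L),
                    width = width, flag = "0")
      cols[[l + 1L]] <- paste0("[", lo, "-", hi, "]")
    }
  }
  hierarchy(do.call(cbind, cols), name)
}

#' The eight-record worked example
#'
#' A tiny fixture used throughout the documentation and tests: eight records
#' over `age` (leaves 34, 45, 66, 70; level 1 decades; level 2 `"*"`) and
#' `sex` (leaves M, F; level 1 `"*"`). Its lattice has 3 x 2 = 6 schemes, so
#' every search algorithm can be checked against enumeration by hand: under
#' 3-anonymity the optimum is scheme `(2, 0)` at 50% granularity; under
#' 2-anonymity it is `(0, 0)` at 100%.
#'
#' @return List with `data` (an [anon_dataset()]) and `hierarchies`.
#' @export
toy8 <- function() {
  data <- data.frame(
    age = c("34", "34", "45", "45", "66", "70", "66", "70"),
    sex = c("M", "M", "F", "F", "M", "F", "M", "F"),
    stringsAsFactors = FALSE)
  age_h <- hierarchy(cbind(c("34", "45", "66", "70"),
                           c("30-39", "40-49", "60-69", "70-79"),
                           rep("*", 4L)), "age")
  sex_h <- hierarchy(cbind(c("M", "F"), c("*", "*")), "sex")
  list(data = anon_dataset(data, c(age = "quasi_identifying",
                                   sex = "quasi_identifying")),
       hierarchies = list(age = age_h, sex = sex_h))
}

#' Quality-versus-budget benchmark harness
#'
#' Runs a plan of (algorithm, privacy model, budget) combinations on a
#' dataset, each repeated `repetitions` times with seeds `seed`, `seed + 1`,
#' ..., and collects a long-format results table. Wall-clock timings are
#' recorded but never asserted against — budgets expressed in evaluations
#' keep results hardware-independent. Individual run failures are recorded
#' in the table and do not stop the remaining runs.
#'
#' @param data,hierarchies the dataset and hierarchies to anonymize.
#' @param plan data frame (or list of lists) with columns/fields `algorithm`
#'   and optionally `label`; each row is one benchmark configuration.
#' @param privacy privacy model applied to every run.
#' @param budget [search_budget()] applied to every run.
#' @param repetitions number of repeats per plan row (default 5).
#' @param seed base seed.
#' @param ga [ga_config()] for genetic runs.
#' @return Data frame with one row per run: `label`, `algorithm`, `rep`,
#'   `seed`, `quality`, `n_suppressed`, `evaluations`, `elapsed`, `error`.
#' @export
run_benchmark <- function(data, hierarchies, plan, privacy = k_anonymity(5L),
                          budget = search_budget(max_evaluations = 100L),
                          repetitions = 5L, seed = 1L, ga = ga_config()) {
  if (is.data.frame(plan)) plan <- split(plan, seq_len(nrow(plan)))
  stopifnot(length(plan) >= 1L)
  rows <- list()
  for (p in plan) {
    p <- as.list(p)
    label <- p$label %||% p$algorithm
    for (rep_i in seq_len(repetitions)) {
      run_seed <- seed + rep_i - 1L
      t0 <- proc.time()[["elapsed"]]
      fit <- tryCatch(
        anonymize(data, hierarchies, privacy, algorithm = p$algorithm,
                  budget = budget, ga = ga, seed = run_seed),
        error = function(e) e)
      elapsed <- proc.time()[["elapsed"]] - t0
      failed <- inherits(fit, "error")
      rows[[length(rows) + 1L]] <- data.frame(
        label = label, algorithm = p$algorithm, rep = rep_i, seed = run_seed,
        quality = if (failed) NA_real_ else fit$quality,
        n_suppressed = if (failed) NA_integer_ else fit$n_suppressed,
        evaluations = if (failed) NA_integer_ else fit$evaluations,
        elapsed = elapsed,
        error = if (failed) conditionMessage(fit) else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a benchmark table to per-configuration means
#' @param results table from [run_benchmark()].
#' @export
aggregate_benchmark <- function(results) {
  ok <- results[!is.na(results$quality), ]
  stats::aggregate(cbind(quality, elapsed) ~ label + algorithm, data = ok,
                   FUN = mean)
}
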