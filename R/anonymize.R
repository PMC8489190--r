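#' Anonymize microdata by generalization and suppression
#'
#' The package's central fitting-style function. It builds the search context
#' from the data, the per-attribute generalization hierarchies and the
#' privacy model, searches the lattice of generalization schemes with the
#' requested algorithm — maximizing post-suppression granularity quality —
#' and returns a classed result with the transformed data, the scheme(s),
#' the quality score and the search trace.
#'
#' @param data an [anon_dataset()], or a data frame combined with `roles`.
#' @param hierarchies named list of [hierarchy()] objects covering every
#'   quasi-identifying attribute.
#' @param privacy [k_anonymity()] or [population_uniqueness()] model
#'   (default `k_anonymity(5)`).
#' @param algorithm lattice search to use: `"exhaustive"` (optimal, small
#'   lattices only), `"bottom_up"` / `"top_down"` (greedy best-first), or
#'   `"genetic"`.
#' @param transformation `"global"` (one scheme for all records) or
#'   `"local"` (iterative multi-scheme recoding, see [anonymize_local()]).
#' @param roles attribute roles when `data` is a plain data frame.
#' @param budget optional [search_budget()].
#' @param ga [ga_config()] for the genetic algorithm.
#' @param local_iterations partition rounds for local recoding (default 100).
#' @param seed integer seed for randomized searches (default 1).
#' @param suppression_token token written into suppressed cells (default
#'   `"*"`).
#' @param exhaustive_cap lattice-size cap for the exhaustive search.
#' @return Object of class `"anonymization"` with components `result`
#'   (output table via [as.data.frame()]), `scheme` (global) or per-record
#'   schemes (local), `quality` (percent), `n_suppressed`, `evaluations`,
#'   `trace`, and the echoed configuration. Methods: `print`, `summary`,
#'   `plot` (quality vs. evaluations), `as.data.frame`.
#' @examples
#' toy <- toy8()
#' fit <- anonymize(toy$data, toy$hierarchies, k_anonymity(3))
#' fit$scheme   # c(2, 0): age fully generalized, sex untouched
#' fit$quality  # 50
#' @export
anonymize <- function(data, hierarchies, privacy = k_anonymity(5L),
                      algorithm = c("exhaustive", "bottom_up", "top_down",
                                    "genetic"),
                      transformation = c("global", "local"),
                      roles = NULL, budget = NULL, ga = ga_config(),
                      local_iterations = 100L, seed = 1L,
                      suppression_token = "*", exhaustive_cap = 1e5) {
  algorithm <- match.arg(algorithm)
  transformation <- match.arg(transformation)
  ctx <- anon_context(data, hierarchies, privacy, roles = roles,
                      suppression_token = suppression_token)
  if (transformation == "global") {
    res <- switch(algorithm,
      exhaustive = search_exhaustive(ctx, cap = exhaustive_cap),
      bottom_up = search_greedy(ctx, "bottom_up", budget),
      top_down = search_greedy(ctx, "top_down", budget),
      genetic = search_genetic(ctx, ga, budget, seed = seed))
    t <- suppress_to_satisfy(apply_scheme(ctx, res$scheme))
    out <- list(transformed = t, scheme = res$scheme, schemes = NULL,
                quality = res$quality, n_suppressed = res$n_suppressed,
                evaluations = res$evaluations, trace = res$trace,
                batches = NULL)
  } else {
    res <- anonymize_local(ctx, inner_algorithm = algorithm,
                           iterations = local_iterations, budget = budget,
                           ga = ga, seed = seed,
                           exhaustive_cap = exhaustive_cap)
    out <- list(transformed = res$transformed, scheme = NULL,
                schemes = res$transformed$schemes,
                quality = res$quality, n_suppressed = res$n_suppressed,
                evaluations = res$evaluations, trace = NULL,
                batches = res$batches)
  }
  structure(c(out, list(ctx = ctx, algorithm = algorithm,
                        transformation = transformation, privacy = privacy,
                        seed = seed, n = ctx$n,
                        heights = ctx$heights)),
            class = "anonymization")
}

#' @export
print.anonymization <- function(x, ...) {
  cat("Anonymization (", x$transformation, " recoding, ", x$algorithm,
      " search, ", format(x$privacy), ")\n", sep = "")
  if (!is.null(x$scheme))
    cat("  scheme: [", paste(x$scheme, collapse = ", "), "]\n", sep = "")
  else
    cat("  ", length(x$batches), " per-partition scheme(s)\n", sep = "")
  cat("  quality: ", formatC(x$quality, format = "f", digits = 1),
      "%   suppressed: ", x$n_suppressed, "/", x$n,
      "   evaluations: ", x$evaluations, "\n", sep = "")
  invisible(x)
}

#' @export
summary.anonymization <- function(object, ...) {
  ec <- equivalence_classes(object$transformed)
  structure(list(fit = object, class_sizes = ec$sizes,
                 n_classes = length(ec$sizes),
                 min_class = if (length(ec$sizes)) min(ec$sizes) else NA,
                 satisfied = is_satisfied(object$transformed)),
            class = "summary.anonymization")
}

#' @export
print.summary.anonymization <- function(x, ...) {
  print(x$fit)
  cat("  equivalence classes: ", x$n_classes, " (smallest: ", x$min_class,
      "); privacy model satisfied: ", x$satisfied, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.anonymization <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  as.data.frame(x$transformed)
}

#' @export
plot.anonymization <- function(x, ...) {
  if (is.null(x$trace) || nrow(x$trace) == 0L) {
    warning("no search trace to plot (local recoding result)")
    return(invisible(x))
  }
  tr <- x$trace
  graphics::plot(tr$evaluations, tr$quality, type = "s",
                 xlab = "scheme evaluations", ylab = "best quality [%]",
                 main = paste0(x$algorithm, " search progress"),
                 ylim = c(0, 100), ...)
  graphics::points(tr$evaluations, tr$quality, pch = 20)
  invisible(x)
}
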