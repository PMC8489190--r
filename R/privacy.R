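#' Privacy models
#'
#' Two privacy models decide whether a transformed dataset is safe to
#' release:
#'
#' * **k-anonymity** — every equivalence class must contain at least `k`
#'   records, i.e. each record is indistinguishable from at least `k - 1`
#'   others on the quasi-identifiers. A strict, purely combinatorial model;
#'   `k = 5` is a common recommendation.
#' * **Population uniqueness** — the estimated fraction of records in the
#'   *population* that are unique on the quasi-identifiers must not exceed a
#'   threshold (e.g. 1%). The dataset is treated as a sample with known
#'   sampling fraction and the population is extrapolated with Pitman's
#'   two-parameter Poisson-Dirichlet model (see [fit_pitman()]). A weaker,
#'   statistical model.
#'
#' @param k minimum equivalence-class size (integer >= 1).
#' @return A classed list usable as the `privacy` argument of
#'   [anon_context()] and [anonymize()].
#' @examples
#' k_anonymity(5)
#' population_uniqueness(threshold = 0.01, sampling_fraction = 0.1)
#' @export
k_anonymity <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be an integer >= 1")
  structure(list(k = k), class = c("k_anonymity", "privacy_model"))
}

#' @rdname k_anonymity
#' @param threshold maximum tolerated fraction of population uniques, in
#'   `[0, 1]`.
#' @param sampling_fraction fraction of the population present in the
#'   dataset, in `(0, 1]`.
#' @export
population_uniqueness <- function(threshold, sampling_fraction) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  if (!is.numeric(sampling_fraction) || sampling_fraction <= 0 ||
      sampling_fraction > 1)
    stop("sampling_fraction must lie in (0, 1]")
  structure(list(threshold = threshold, sampling_fraction = sampling_fraction),
            class = c("population_uniqueness", "privacy_model"))
}

#' @export
format.privacy_model <- function(x, ...) {
  if (inherits(x, "k_anonymity")) sprintf("%d-anonymity", x$k)
  else sprintf("population uniqueness <= %g (sampling fraction %g)",
               x$threshold, x$sampling_fraction)
}

#' @export
print.privacy_model <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Check k-anonymity of a class-size histogram
#'
#' @param sizes integer vector of equivalence-class sizes.
#' @param k minimum class size.
#' @return `TRUE` iff every class has at least `k` records; an empty
#'   histogram is vacuously k-anonymous.
#' @export
check_k_anonymity <- function(sizes, k) {
  if (k < 1) stop("k must be >= 1")
  length(sizes) == 0L || all(sizes >= k)
}

#' Is a transformed dataset safe under a privacy model?
#'
#' Dispatches on the model: k-anonymity checks every class size; population
#' uniqueness compares the Pitman-based estimate with the threshold. An empty
#' output (everything suppressed) satisfies both models by definition.
#'
#' @param t an `"anon_transformed"` object.
#' @param model a privacy model; defaults to the context's.
#' @return `TRUE` or `FALSE`.
#' @export
is_satisfied <- function(t, model = NULL) {
  model <- model %||% t$ctx$privacy
  ec <- equivalence_classes(t)
  if (ec$n_effective == 0L) return(TRUE)
  if (inherits(model, "k_anonymity"))
    return(check_k_anonymity(ec$sizes, model$k))
  if (inherits(model, "population_uniqueness"))
    return(estimate_population_uniqueness(ec$sizes, model$sampling_fraction) <=
             model$threshold)
  stop("unknown privacy model of class ", paste(class(model), collapse = "/"))
}
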