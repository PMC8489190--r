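#' Parse a run configuration file
#'
#' Reads a YAML run configuration and validates it into a fully defaulted
#' `RunConfig` list. Required keys: `input` (path), `quasi_identifiers`
#' (mapping attribute -> hierarchy path) and a `privacy` block with
#' `model: k_anonymity` plus `k`, or `model: population_uniqueness` plus
#' `threshold` and `sampling_fraction` — there is no silent default for `k`.
#' Optional keys with defaults: `delimiter` (","), `hierarchy_delimiter`
#' (";"), `identifying` / `insensitive` attribute lists, `algorithm`
#' (`exhaustive`), `transformation` (`global`), `local_iterations` (100),
#' `suppression_token` ("*"), `seed` (1), `budget` (`time_limit`,
#' `max_evaluations`), and a `genetic` block whose entries override the
#' standard [ga_config()] values. Unknown keys and invalid values raise
#' errors naming the key.
#'
#' @param path YAML file.
#' @return A validated list of class `"run_config"`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("input", "delimiter", "hierarchy_delimiter", "quasi_identifiers",
             "identifying", "insensitive", "privacy", "quality", "algorithm",
             "transformation", "local_iterations", "suppression_token",
             "seed", "budget", "genetic", "output", "report")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  need <- function(key) {
    if (is.null(raw[[key]])) stop("missing configuration key: ", key)
    raw[[key]]
  }
  cfg <- list(
    input = need("input"),
    delimiter = raw$delimiter %||% ",",
    hierarchy_delimiter = raw$hierarchy_delimiter %||% ";",
    quasi_identifiers = need("quasi_identifiers"),
    identifying = as.character(raw$identifying %||% character()),
    insensitive = as.character(raw$insensitive %||% character()),
    quality = raw$quality %||% "granularity",
    algorithm = raw$algorithm %||% "exhaustive",
    transformation = raw$transformation %||% "global",
    local_iterations = as.integer(raw$local_iterations %||% 100L),
    suppression_token = raw$suppression_token %||% "*",
    seed = as.integer(raw$seed %||% 1L),
    output = raw$output %||% NULL,
    report = raw$report %||% NULL)
  if (!identical(cfg$quality, "granularity"))
    stop("quality: only the granularity model is supported")
  if (!cfg$algorithm %in% c("exhaustive", "bottom_up", "top_down", "genetic"))
    stop("algorithm: must be one of exhaustive, bottom_up, top_down, genetic")
  if (!cfg$transformation %in% c("global", "local"))
    stop("transformation: must be global or local")
  if (length(cfg$quasi_identifiers) == 0L ||
      is.null(names(cfg$quasi_identifiers)) ||
      any(!nzchar(names(cfg$quasi_identifiers))))
    stop("quasi_identifiers: must map each attribute name to a hierarchy path")
  missing_h <- names(cfg$quasi_identifiers)[
    !vapply(cfg$quasi_identifiers, function(p)
      is.character(p) && nzchar(p), logical(1))]
  if (length(missing_h))
    stop("quasi_identifiers: missing hierarchy path for attribute(s): ",
         paste(missing_h, collapse = ", "))
  priv <- need("privacy")
  model <- priv$model %||% stop("privacy: missing 'model'")
  cfg$privacy <- switch(model,
    k_anonymity = {
      if (is.null(priv$k)) stop("privacy: k_anonymity requires 'k'")
      k_anonymity(priv$k)
    },
    population_uniqueness = {
      if (is.null(priv$threshold) || is.null(priv$sampling_fraction))
        stop("privacy: population_uniqueness requires 'threshold' and ",
             "'sampling_fraction'")
      population_uniqueness(priv$threshold, priv$sampling_fraction)
    },
    stop("privacy: unknown model ", dQuote(model, FALSE)))
  gb <- raw$budget
  cfg$budget <- if (is.null(gb)) NULL else
    search_budget(time_limit = gb$time_limit,
                  max_evaluations = gb$max_evaluations)
  ga_args <- raw$genetic %||% list()
  unknown_ga <- setdiff(names(ga_args), names(formals(ga_config)))
  if (length(unknown_ga))
    stop("genetic: unknown key(s): ", paste(unknown_ga, collapse = ", "))
  cfg$ga <- tryCatch(do.call(ga_config, ga_args), error = function(e)
    stop("genetic: ", conditionMessage(e), call. = FALSE))
  structure(cfg, class = "run_config")
}

load_run_inputs <- function(cfg) {
  if (!file.exists(cfg$input)) stop("input file not found: ", cfg$input)
  roles <- c(setNames(rep("quasi_identifying", length(cfg$quasi_identifiers)),
                      names(cfg$quasi_identifiers)),
             setNames(rep("identifying", length(cfg$identifying)),
                      cfg$identifying))
  data <- read_dataset(cfg$input, cfg$delimiter, roles)
  hiers <- lapply(cfg$quasi_identifiers, read_hierarchy,
                  delimiter = cfg$hierarchy_delimiter)
  for (a in names(hiers)) attr(hiers[[a]], "attribute") <- a
  list(data = data, hierarchies = hiers)
}

config_echo <- function(cfg) {
  list(input = cfg$input, delimiter = cfg$delimiter,
       hierarchy_delimiter = cfg$hierarchy_delimiter,
       quasi_identifiers = as.list(cfg$quasi_identifiers),
       identifying = cfg$identifying, insensitive = cfg$insensitive,
       quality = cfg$quality, algorithm = cfg$algorithm,
       transformation = cfg$transformation,
       local_iterations = cfg$local_iterations,
       suppression_token = cfg$suppression_token, seed = cfg$seed,
       privacy = if (inherits(cfg$privacy, "k_anonymity"))
         list(model = "k_anonymity", k = cfg$privacy$k)
       else list(model = "population_uniqueness",
                 threshold = cfg$privacy$threshold,
                 sampling_fraction = cfg$privacy$sampling_fraction),
       budget = if (is.null(cfg$budget)) NULL else
         Filter(Negate(is.null), unclass(cfg$budget)),
       genetic = unclass(cfg$ga),
       output = cfg$output, report = cfg$report)
}

#' Run a configured anonymization end to end
#'
#' Loads the input microdata and hierarchies named in a [parse_config()]
#' result, runs [anonymize()], writes the output microdata (if `output` is
#' configured) and a YAML run report (if `report` is configured) containing
#' the chosen scheme(s), quality, suppressed count, evaluation count,
#' elapsed time, seed and the full effective configuration. No partial
#' output file is left behind on error.
#'
#' @param cfg a `"run_config"` (or path to one).
#' @param quiet suppress the console summary.
#' @return The `"anonymization"` object, invisibly; status 0 semantics are
#'   handled by the command-line wrapper.
#' @export
cmd_anonymize <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- parse_config(cfg)
  inputs <- load_run_inputs(cfg)
  t0 <- proc.time()[["elapsed"]]
  fit <- anonymize(inputs$data, inputs$hierarchies, cfg$privacy,
                   algorithm = cfg$algorithm,
                   transformation = cfg$transformation,
                   budget = cfg$budget, ga = cfg$ga,
                   local_iterations = cfg$local_iterations, seed = cfg$seed,
                   suppression_token = cfg$suppression_token)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!is.null(cfg$output))
    write_dataset(as.data.frame(fit), cfg$output, cfg$delimiter)
  if (!is.null(cfg$report)) {
    report <- list(
      scheme = if (!is.null(fit$scheme)) as.integer(fit$scheme) else
        lapply(fit$batches, function(b)
          list(iteration = b$iteration, scheme = as.integer(b$scheme),
               n_records = b$n_rescued)),
      quality_percent = fit$quality,
      suppressed = fit$n_suppressed,
      evaluations = fit$evaluations,
      elapsed_seconds = elapsed,
      seed = cfg$seed,
      config = config_echo(cfg))
    yaml::write_yaml(report, cfg$report)
  }
  if (!quiet) print(fit)
  invisible(fit)
}

#' Estimate re-identification risk for a configured dataset
#'
#' Reads the configured input, groups the untransformed records into
#' equivalence classes on the quasi-identifiers, fits the Pitman model and
#' prints the estimated population uniqueness together with the fitted
#' parameters and the convergence flag.
#'
#' @param cfg a `"run_config"` (or path); its privacy block must carry a
#'   `sampling_fraction` (model `population_uniqueness`).
#' @param quiet suppress printing.
#' @return List with `estimate`, `fit` (a `"pitman_fit"` or `NULL` for an
#'   empty dataset), invisibly printed unless `quiet`.
#' @export
cmd_estimate_risk <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- parse_config(cfg)
  if (!inherits(cfg$privacy, "population_uniqueness"))
    stop("estimate-risk requires privacy model population_uniqueness")
  inputs <- load_run_inputs(cfg)
  ctx <- anon_context(inputs$data, inputs$hierarchies, cfg$privacy)
  t <- apply_scheme(ctx, rep(0L, length(ctx$heights)))
  ec <- equivalence_classes(t)
  pi <- cfg$privacy$sampling_fraction
  if (ec$n_effective == 0L) {
    out <- list(estimate = 0, fit = NULL, degenerate = TRUE)
  } else {
    fit <- fit_pitman(ec$sizes)
    est <- estimate_population_uniqueness(ec$sizes, pi, fit = fit)
    out <- list(estimate = est, fit = fit, degenerate = fit$degenerate)
  }
  if (!quiet) {
    cat(sprintf("Estimated population uniqueness: %.6f (sampling fraction %g)\n",
                out$estimate, pi))
    if (!is.null(out$fit)) print(out$fit)
    else cat("empty dataset; degenerate estimate\n")
  }
  invisible(out)
}
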