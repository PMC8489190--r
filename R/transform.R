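#' Anonymization context
#'
#' Bundles a dataset, the hierarchies of its quasi-identifiers, a privacy
#' model and bookkeeping that the search algorithms reuse across thousands of
#' candidate schemes: per attribute, each record's leaf index and the
#' hierarchy value and granularity loss at every level. Building the context
#' validates that every observed quasi-identifier value is a hierarchy leaf.
#'
#' @param data an [anon_dataset()] (or data frame plus `roles`).
#' @param hierarchies named list of [hierarchy()] objects, one per
#'   quasi-identifying attribute.
#' @param privacy a privacy model, e.g. [k_anonymity()] or
#'   [population_uniqueness()].
#' @param roles attribute roles, used when `data` is a plain data frame.
#' @param suppression_token string written into the quasi-identifier cells of
#'   suppressed records (default `"*"`).
#' @return An object of class `"anon_context"`.
#' @export
anon_context <- function(data, hierarchies, privacy = k_anonymity(5L),
                         roles = NULL, suppression_token = "*") {
  if (!inherits(data, "anon_dataset"))
    data <- anon_dataset(data, roles %||% character())
  qi <- quasi_identifiers(data)
  missing_h <- setdiff(qi, names(hierarchies))
  if (length(missing_h))
    stop("no hierarchy for quasi-identifying attribute(s): ",
         paste(missing_h, collapse = ", "))
  n <- nrow(data)
  attrs <- vector("list", length(qi))
  names(attrs) <- qi
  for (a in qi) {
    h <- hierarchies[[a]]
    tab <- unclass(h)
    viol <- validate_hierarchy(h, observed = data[[a]])
    if (length(viol))
      stop("attribute ", dQuote(a, FALSE), ": ", paste(viol, collapse = "; "))
    leaf_idx <- match(data[[a]], tab[, 1L])
    D <- nrow(tab)
    L <- ncol(tab) - 1L
    # codes[r, l+1]: integer code of record r's value at level l;
    # loss[r, l+1]: granularity loss of that cell
    codes <- matrix(0L, nrow = n, ncol = L + 1L)
    loss <- matrix(0, nrow = n, ncol = L + 1L)
    values <- vector("list", L + 1L)
    nlev <- integer(L + 1L)
    for (l in 0:L) {
      col <- tab[, l + 1L]
      uvals <- unique(col)
      code_by_leaf <- match(col, uvals)
      leaves_per_val <- tabulate(code_by_leaf, nbins = length(uvals))
      codes[, l + 1L] <- code_by_leaf[leaf_idx]
      loss[, l + 1L] <- if (D > 1L)
        (leaves_per_val[codes[, l + 1L]] - 1) / (D - 1) else 0
      values[[l + 1L]] <- uvals
      nlev[l + 1L] <- length(uvals)
    }
    attrs[[a]] <- list(hierarchy = h, height = L, n_leaves = D,
                       leaf_idx = leaf_idx, codes = codes, loss = loss,
                       values = values, n_values = nlev)
  }
  structure(list(data = data, qi = qi, attrs = attrs,
                 heights = vapply(attrs, `[[`, integer(1), "height"),
                 privacy = privacy, token = suppression_token,
                 n = n),
            class = "anon_context")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.anon_context <- function(x, ...) {
  cat("Anonymization context: ", x$n, " records, ", length(x$qi),
      " quasi-identifiers\n", sep = "")
  cat("  heights: [", paste(x$heights, collapse = ", "), "], lattice size ",
      format(lattice_size(x$heights), big.mark = ","), "\n", sep = "")
  cat("  privacy: ", format(x$privacy), "\n", sep = "")
  invisible(x)
}

# Integer class ids of all records under scheme g (mixed-radix key),
# optionally restricted to the records in `subset` (integer indices).
class_ids <- function(ctx, g, subset = NULL) {
  idx <- subset %||% seq_len(ctx$n)
  if (length(ctx$qi) == 0L || length(idx) == 0L)
    return(rep(1L, length(idx)))
  key <- numeric(length(idx))
  radix <- 1
  for (i in seq_along(ctx$qi)) {
    a <- ctx$attrs[[i]]
    key <- key + radix * (a$codes[idx, g[i] + 1L] - 1)
    radix <- radix * a$n_values[g[i] + 1L]
  }
  match(key, unique(key))
}

#' Apply a generalization scheme (global recoding)
#'
#' Replaces every quasi-identifier cell by its hierarchy value at the level
#' the scheme assigns to that attribute; all other cells are untouched and no
#' record is suppressed. Use [suppress_to_satisfy()] afterwards to enforce a
#' privacy model.
#'
#' @param ctx an [anon_context()].
#' @param scheme integer level vector, one entry per quasi-identifier.
#' @return An object of class `"anon_transformed"`: list with `data` (the
#'   recoded data frame), `suppressed` (logical vector), `scheme` (the vector
#'   applied), `schemes` (per-record scheme matrix, for local recoding) and
#'   `token`.
#' @export
apply_scheme <- function(ctx, scheme) {
  scheme <- as.integer(scheme)
  check_scheme(ctx, scheme)
  data <- as.data.frame(ctx$data)
  for (i in seq_along(ctx$qi)) {
    a <- ctx$attrs[[i]]
    data[[ctx$qi[i]]] <- a$values[[scheme[i] + 1L]][a$codes[, scheme[i] + 1L]]
  }
  schemes <- matrix(scheme, nrow = ctx$n, ncol = length(scheme), byrow = TRUE)
  structure(list(data = data, suppressed = rep(FALSE, ctx$n),
                 scheme = scheme, schemes = schemes, token = ctx$token,
                 ctx = ctx),
            class = "anon_transformed")
}

check_scheme <- function(ctx, scheme) {
  if (length(scheme) != length(ctx$qi))
    stop("scheme has ", length(scheme), " levels but there are ",
         length(ctx$qi), " quasi-identifiers")
  if (any(scheme < 0L) || any(scheme > ctx$heights))
    stop("scheme [", paste(scheme, collapse = ", "),
         "] outside lattice bounds [", paste(ctx$heights, collapse = ", "), "]")
  invisible(scheme)
}

#' Equivalence classes of a transformed dataset
#'
#' Partitions the non-suppressed records by their full tuple of generalized
#' quasi-identifier values. Records in the same class are indistinguishable
#' with respect to the quasi-identifiers — the basis of k-anonymity.
#'
#' @param t an `"anon_transformed"` object from [apply_scheme()].
#' @return List with `sizes` (integer class-size histogram), `groups` (list of
#'   record-index vectors, first-occurrence order) and `n_effective`
#'   (number of non-suppressed records).
#' @export
equivalence_classes <- function(t) {
  stopifnot(inherits(t, "anon_transformed"))
  keep <- which(!t$suppressed)
  if (length(keep) == 0L)
    return(list(sizes = integer(), groups = list(), n_effective = 0L))
  qi <- t$ctx$qi
  if (length(qi) == 0L)
    return(list(sizes = length(keep), groups = list(keep),
                n_effective = length(keep)))
  key <- do.call(paste, c(unname(as.list(t$data[keep, qi, drop = FALSE])),
                          sep = "\r"))
  id <- match(key, unique(key))
  groups <- split(keep, id)
  names(groups) <- NULL
  groups <- groups[order(vapply(groups, `[[`, integer(1), 1L))]
  list(sizes = lengths(groups), groups = groups, n_effective = length(keep))
}

#' Suppress records until a privacy model is satisfied
#'
#' Under k-anonymity, exactly the records lying in equivalence classes of size
#' `< k` are suppressed. Under a population-uniqueness threshold, whole
#' classes are suppressed in ascending order of class size (ties broken by
#' first occurrence) until the uniqueness estimate on the remaining records
#' meets the threshold. Suppression replaces every quasi-identifier cell with
#' the suppression token; suppressed records stay in the output table but are
#' excluded from privacy evaluation. Suppressing everything always satisfies
#' both models, so this never fails.
#'
#' @param t an `"anon_transformed"` object.
#' @param model a privacy model; defaults to the context's.
#' @return The transformed object with its suppression set (possibly) grown.
#' @export
suppress_to_satisfy <- function(t, model = NULL) {
  stopifnot(inherits(t, "anon_transformed"))
  model <- model %||% t$ctx$privacy
  ec <- equivalence_classes(t)
  drop_idx <- suppression_plan(ec, model)
  if (length(drop_idx)) {
    t$suppressed[drop_idx] <- TRUE
    t$data[drop_idx, t$ctx$qi] <- t$token
  }
  t
}

# Which record indices must be suppressed, given equivalence classes.
suppression_plan <- function(ec, model) {
  if (length(ec$sizes) == 0L) return(integer())
  if (inherits(model, "k_anonymity")) {
    small <- which(ec$sizes < model$k)
    return(unlist(ec$groups[small], use.names = FALSE) %||% integer())
  }
  if (inherits(model, "population_uniqueness")) {
    sizes <- ec$sizes
    ord <- order(sizes)            # ascending size, first-occurrence ties
    alive <- rep(TRUE, length(sizes))
    i <- 1L
    while (any(alive)) {
      est <- estimate_population_uniqueness(sizes[alive], model$sampling_fraction)
      if (est <= model$threshold) break
      alive[ord[i]] <- FALSE
      i <- i + 1L
    }
    return(unlist(ec$groups[!alive], use.names = FALSE) %||% integer())
  }
  stop("unknown privacy model of class ", paste(class(model), collapse = "/"))
}

#' Granularity quality score
#'
#' Scores a transformed dataset on the value-level precision that survives
#' anonymization. Each quasi-identifier cell contributes a loss of
#' `(leaves(v) - 1) / (D - 1)`, where `leaves(v)` is the number of distinct
#' original values the cell's generalized value `v` covers and `D` is the
#' attribute's total leaf count (loss 0 when `D = 1`); a suppressed cell
#' loses everything (loss 1). The score is `100 * (1 - mean loss)` over all
#' quasi-identifier cells of all records: 100% for unmodified data, 0% when
#' all information has been removed. Datasets with no records or no
#' quasi-identifiers score 100.
#'
#' @param t an `"anon_transformed"` object.
#' @return Quality percentage in `[0, 100]`.
#' @export
quality_granularity <- function(t) {
  stopifnot(inherits(t, "anon_transformed"))
  ctx <- t$ctx
  m <- length(ctx$qi)
  if (ctx$n == 0L || m == 0L) return(100)
  total <- 0
  keep <- !t$suppressed
  for (i in seq_len(m)) {
    a <- ctx$attrs[[i]]
    lv <- t$schemes[, i] + 1L
    cell_loss <- a$loss[cbind(seq_len(ctx$n), lv)]
    total <- total + sum(cell_loss[keep])
  }
  total <- total + sum(!keep) * m   # suppressed cells: loss 1 each
  100 * (1 - total / (ctx$n * m))
}

#' @export
print.anon_transformed <- function(x, ...) {
  cat("Transformed microdata: ", nrow(x$data), " records, ",
      sum(x$suppressed), " suppressed\n", sep = "")
  if (!is.null(x$scheme))
    cat("  scheme: [", paste(x$scheme, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Extract the output table of a transformation or anonymization
#'
#' Directly identifying attributes are dropped; suppressed records keep their
#' row but carry the suppression token in every quasi-identifier cell.
#'
#' @param x an `"anon_transformed"` object.
#' @param row.names,optional,... passed on conventions of the generic,
#'   ignored.
#' @export
as.data.frame.anon_transformed <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  roles <- attribute_roles(x$ctx$data)
  keep_cols <- names(roles)[roles != "identifying"]
  out <- x$data[, keep_cols, drop = FALSE]
  rownames(out) <- NULL
  out
}
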