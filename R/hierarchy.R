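#' Generalization hierarchies
#'
#' A generalization hierarchy describes, for one quasi-identifying attribute,
#' how its original values (level 0, the "leaves") are progressively coarsened
#' into broader categories, up to a single root value at the top level (e.g.
#' age `34` -> decade `30-39` -> `*`). It is stored as a character matrix with
#' one row per leaf and one column per level: column `l + 1` holds the value at
#' generalization level `l`.
#'
#' Structural requirements: leaves (column 1) are pairwise distinct; for every
#' level the mapping to the next level is functional (two rows sharing a value
#' at level `l` also share it at level `l + 1`); the number of distinct values
#' per column never increases with the level.
#'
#' @param table character matrix (or data frame) of hierarchy rows, one column
#'   per level, leaves in column 1.
#' @param attribute name of the attribute this hierarchy generalizes.
#' @return An object of class `"anon_hierarchy"`: the character matrix with
#'   attributes `attribute` (name) and `height` (the maximum level `L`,
#'   `ncol(table) - 1`).
#' @examples
#' h <- hierarchy(cbind(c("male", "female"), c("*", "*")), "sex")
#' hierarchy_height(h)  # 1
#' @export
hierarchy <- function(table, attribute = "") {
  if (is.data.frame(table)) table <- as.matrix(table)
  if (!is.matrix(table)) table <- matrix(table, ncol = 1L)
  storage.mode(table) <- "character"
  if (ncol(table) < 1L) stop("hierarchy must have at least one column")
  structure(table,
            attribute = as.character(attribute),
            height = ncol(table) - 1L,
            class = "anon_hierarchy")
}

#' @rdname hierarchy
#' @param h an `anon_hierarchy`.
#' @export
hierarchy_height <- function(h) attr(h, "height")

#' @rdname hierarchy
#' @export
hierarchy_leaves <- function(h) unname(h[, 1L])

#' Read a generalization hierarchy from a delimited text file
#'
#' The file holds one row per leaf value: the leaf followed by its generalized
#' value at each successive level (leaf-to-root path), no header. The default
#' delimiter is `";"`, the de-facto convention for hierarchy CSV files.
#'
#' @param path file to read.
#' @param delimiter single-character field separator (default `";"`).
#' @param attribute attribute name to record; defaults to the file name
#'   without extension.
#' @param validate if `TRUE` (default), structural violations raise an error.
#' @return An [hierarchy()] object.
#' @export
read_hierarchy <- function(path, delimiter = ";", attribute = NULL,
                           validate = TRUE) {
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  if (is.null(attribute)) attribute <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) | seq_along(lines) < length(lines)]
  if (length(lines) == 0L) stop("hierarchy file is empty: ", path)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(cells)
  # strsplit drops a trailing empty field; pad rows ending in the delimiter
  pad <- endsWith(lines, delimiter)
  widths[pad] <- widths[pad] + 1L
  if (length(unique(widths)) != 1L)
    stop("ragged hierarchy file ", path, ": rows have differing widths (",
         paste(sort(unique(widths)), collapse = ", "), ")")
  w <- widths[[1L]]
  if (w == 0L) stop("hierarchy file ", path, " has zero-width rows")
  tab <- matrix("", nrow = length(cells), ncol = w)
  for (i in seq_along(cells)) tab[i, seq_along(cells[[i]])] <- cells[[i]]
  h <- hierarchy(tab, attribute)
  if (validate) {
    viol <- validate_hierarchy(h)
    if (length(viol)) stop("invalid hierarchy in ", path, ": ",
                           paste(viol, collapse = "; "))
  }
  h
}

#' Write a hierarchy back to delimited text (round-trips with
#' [read_hierarchy()]).
#' @inheritParams read_hierarchy
#' @param h an `anon_hierarchy`.
#' @export
write_hierarchy <- function(h, path, delimiter = ";") {
  writeLines(apply(unclass(h), 1L, paste, collapse = delimiter), path)
  invisible(path)
}

#' Validate a generalization hierarchy
#'
#' Checks the structural invariants of a hierarchy and, optionally, that a set
#' of observed attribute values is covered by its leaves. Violations are
#' returned, not raised, so callers can report them all at once.
#'
#' @param h an [hierarchy()] object (or bare character matrix).
#' @param observed character vector of values observed in the data; each must
#'   appear among the leaves.
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_hierarchy <- function(h, observed = character()) {
  tab <- unclass(h)
  viol <- character()
  leaves <- tab[, 1L]
  dup <- unique(leaves[duplicated(leaves)])
  if (length(dup))
    viol <- c(viol, paste0("duplicate leaf value(s): ",
                           paste(dQuote(dup, FALSE), collapse = ", ")))
  if (ncol(tab) > 1L) {
    for (l in seq_len(ncol(tab) - 1L)) {
      split_up <- split(tab[, l + 1L], tab[, l])
      bad <- names(split_up)[vapply(split_up, function(v)
        length(unique(v)) > 1L, logical(1))]
      if (length(bad))
        viol <- c(viol, paste0("level ", l - 1L, " value(s) ",
                               paste(dQuote(bad, FALSE), collapse = ", "),
                               " map to multiple level-", l, " values"))
    }
    ndist <- apply(tab, 2L, function(col) length(unique(col)))
    if (any(diff(ndist) > 0L))
      viol <- c(viol, "number of distinct values increases with the level")
  }
  missing <- setdiff(unique(observed), leaves)
  if (length(missing))
    viol <- c(viol, paste0("observed value(s) not covered by the leaves: ",
                           paste(dQuote(missing, FALSE), collapse = ", ")))
  viol
}

#' @export
print.anon_hierarchy <- function(x, ...) {
  cat("Generalization hierarchy for ", dQuote(attr(x, "attribute"), FALSE),
      ": ", nrow(x), " leaves, height ", attr(x, "height"), "\n", sep = "")
  utils::head(as.data.frame(unclass(x)), 6L) |> print(...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}
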