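#' Microdata tables with attribute roles
#'
#' A dataset is a rectangular table of text cells plus a role for each
#' attribute: `"identifying"` attributes (names, IDs) are dropped from any
#' anonymized output, `"quasi_identifying"` attributes (age, sex, ZIP, ...)
#' can re-identify individuals in combination and are the ones generalized and
#' suppressed, and `"insensitive"` attributes pass through untouched.
#' Cells are compared as exact strings: no trimming, case folding, or type
#' coercion, so runs are deterministic. An empty cell `""` is an ordinary
#' value and must appear among the hierarchy leaves if its attribute is a
#' quasi-identifier.
#'
#' @param data data frame of character columns (coerced).
#' @param roles named character vector mapping attribute names to roles;
#'   attributes not named default to `"insensitive"`.
#' @return An object of class `"anon_dataset"`: the data frame with a
#'   `roles` attribute (full named vector, one entry per attribute).
#' @export
anon_dataset <- function(data, roles = character()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data[] <- lapply(data, as.character)
  nm <- names(data)
  if (anyDuplicated(nm)) stop("duplicate attribute names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  roles <- unlist(roles)
  unknown <- setdiff(names(roles), nm)
  if (length(unknown))
    stop("role given for unknown attribute(s): ", paste(unknown, collapse = ", "))
  valid <- c("identifying", "quasi_identifying", "insensitive")
  bad <- setdiff(roles, valid)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "),
                        " (valid: ", paste(valid, collapse = ", "), ")")
  full <- setNames(rep("insensitive", length(nm)), nm)
  full[names(roles)] <- roles
  structure(data, roles = full, class = c("anon_dataset", "data.frame"))
}

#' @rdname anon_dataset
#' @param x an `anon_dataset`.
#' @export
attribute_roles <- function(x) attr(x, "roles")

#' @rdname anon_dataset
#' @export
quasi_identifiers <- function(x) {
  r <- attr(x, "roles")
  names(r)[r == "quasi_identifying"]
}

#' Read a delimited microdata file
#'
#' Reads an RFC-4180-style delimited text file with a header row. Every cell
#' is kept verbatim as text.
#'
#' @param path file to read.
#' @param delimiter single-character field separator (default `","`).
#' @param roles named character vector of attribute roles (see
#'   [anon_dataset()]); attributes not listed are `"insensitive"`.
#' @return An [anon_dataset()].
#' @examples
#' f <- tempfile(); writeLines(c("a,b", "1,x", "2,y"), f)
#' d <- read_dataset(f, roles = c(a = "quasi_identifying"))
#' nrow(d)  # 2
#' @export
read_dataset <- function(path, delimiter = ",", roles = character()) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  nf <- utils::count.fields(path, sep = delimiter, quote = "\"",
                            comment.char = "")
  bad <- which(nf != nf[[1L]])
  if (length(bad))
    stop("ragged row ", bad[[1L]] - 1L, " in ", path, ": ", nf[bad[[1L]]],
         " cells under a ", nf[[1L]], "-column header")
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", fill = FALSE,
                          blank.lines.skip = FALSE, na.strings = NULL)
  anon_dataset(df, roles)
}

#' Write microdata to delimited text (round-trips with [read_dataset()]).
#' @param x data frame to write.
#' @param path output file.
#' @param delimiter field separator (default `","`).
#' @export
write_dataset <- function(x, path, delimiter = ",") {
  utils::write.table(x, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.anon_dataset <- function(x, ...) {
  r <- attr(x, "roles")
  cat("Microdata: ", nrow(x), " records, ", ncol(x), " attributes (",
      sum(r == "quasi_identifying"), " quasi-identifying)\n", sep = "")
  print(as.data.frame(utils::head(x, 6L)), ...)
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more records)\n", sep = "")
  invisible(x)
}
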