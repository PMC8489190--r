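#' Generalization schemes and the solution-space lattice
#'
#' A generalization scheme assigns one hierarchy level to each
#' quasi-identifying attribute: an integer vector `g` with
#' `0 <= g[i] <= heights[i]`. The set of all schemes, ordered componentwise,
#' is a lattice whose bottom is the all-zero vector (no generalization) and
#' whose top is the heights vector (everything generalized to the root). Its
#' size is `prod(heights + 1)` and grows exponentially with the number of
#' attributes.
#'
#' `lattice_size()` uses exact integer arithmetic throughout: real solution
#' spaces exceed 2^46 schemes, so the product is accumulated in an internal
#' arbitrary-precision representation. The result is returned as a double
#' whenever it is exactly representable (below 2^53) and as an exact decimal
#' string otherwise.
#'
#' @param heights non-negative integer vector of per-attribute hierarchy
#'   heights.
#' @return `lattice_size()`: the exact number of schemes (double if < 2^53,
#'   decimal character string otherwise).
#' @examples
#' lattice_size(c(3, 1, 5, 3, 1))  # 384
#' @export
lattice_size <- function(heights) {
  heights <- as.numeric(heights)
  if (length(heights) == 0L) return(1)
  if (any(is.na(heights)) || any(heights < 0) || any(heights != floor(heights)))
    stop("heights must be non-negative integers")
  big <- big_from_num(1)
  for (h in heights) big <- big_mul_small(big, h + 1)
  num <- big_to_num(big)
  if (!is.na(num)) num else big_to_string(big)
}

# Arbitrary-precision non-negative integers as little-endian base-1e4 digit
# vectors. Only what lattice sizes need: multiply by a small integer.
big_from_num <- function(x) {
  digits <- integer()
  repeat {
    digits <- c(digits, x %% 10000)
    x <- x %/% 10000
    if (x == 0) break
  }
  digits
}

big_mul_small <- function(big, m) {
  prod <- big * m
  carry <- 0
  out <- numeric(0)
  i <- 1L
  while (i <= length(prod) || carry > 0) {
    v <- carry + if (i <= length(prod)) prod[i] else 0
    out[i] <- v %% 10000
    carry <- v %/% 10000
    i <- i + 1L
  }
  out
}

big_to_num <- function(big) {
  v <- sum(big * 10000^(seq_along(big) - 1))
  if (v < 2^53) v else NA_real_
}

big_to_string <- function(big) {
  n <- length(big)
  parts <- sprintf("%04d", rev(big))
  parts[1L] <- sub("^0+(?=.)", "", parts[1L], perl = TRUE)
  paste(parts, collapse = "")
}

#' Lattice neighbours of a generalization scheme
#'
#' The up-neighbours of `g` are the schemes obtained by raising exactly one
#' level by 1 (bounded by the heights); down-neighbours lower one level by 1
#' (bounded by 0). Output rows follow coordinate order.
#'
#' @param g integer level vector.
#' @param heights per-attribute heights (same length as `g`).
#' @param direction `"up"` or `"down"`.
#' @return Integer matrix with one neighbour per row (0 rows at the boundary).
#' @export
neighbors <- function(g, heights, direction = c("up", "down")) {
  direction <- match.arg(direction)
  g <- as.integer(g)
  heights <- as.integer(heights)
  stopifnot(length(g) == length(heights), all(g >= 0L), all(g <= heights))
  step <- if (direction == "up") 1L else -1L
  movable <- if (direction == "up") which(g < heights) else which(g > 0L)
  out <- matrix(rep(g, each = length(movable)), nrow = length(movable),
                ncol = length(g))
  if (length(movable))
    out[cbind(seq_along(movable), movable)] <-
      g[movable] + step
  out
}

#' Enumerate every scheme of a lattice (row-wise), in lexicographic order
#' with the last coordinate varying fastest. Intended for small lattices.
#' @inheritParams lattice_size
#' @export
enumerate_schemes <- function(heights) {
  if (length(heights) == 0L) return(matrix(integer(), nrow = 1L, ncol = 0L))
  grids <- lapply(rev(heights), function(h) 0:h)
  g <- as.matrix(rev(expand.grid(grids, KEEP.OUT.ATTRS = FALSE)))
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g[do.call(order, as.data.frame(g)), , drop = FALSE]
}

# lexicographic comparison: TRUE if a < b
scheme_lex_lt <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

scheme_key <- function(g) paste(g, collapse = ",")
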