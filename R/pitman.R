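#' Expected class counts under the Pitman (Poisson-Dirichlet) model
#'
#' Under the two-parameter Poisson-Dirichlet model PD(alpha, theta) with
#' `0 <= alpha < 1`, `theta > -alpha`, a sample of `n` records partitions into
#' equivalence classes whose expected number and expected number of
#' singletons have closed forms in rising factorials. With
#' `x^(r) = Gamma(x + r) / Gamma(x)`:
#'
#' * expected classes: `E K_n = (theta/alpha) * ((theta+alpha)^(n) /
#'   theta^(n) - 1)` for `alpha > 0`, and
#'   `theta * (digamma(theta + n) - digamma(theta))` in the Ewens limit
#'   `alpha = 0`;
#' * expected singleton classes: `E K_{n,1} = n * (theta+alpha)^(n-1) /
#'   (theta+1)^(n-1)`.
#'
#' Both are evaluated with log-gamma arithmetic so that samples of millions of
#' records remain numerically stable.
#'
#' @param theta,alpha Pitman parameters (`theta > -alpha`, `0 <= alpha < 1`).
#' @param n sample size.
#' @return Expected count (double).
#' @keywords internal
pitman_expected_classes <- function(theta, alpha, n) {
  if (n == 0) return(0)
  if (alpha <= 0) {
    return(theta * (digamma(theta + n) - digamma(theta)))
  }
  # (theta/alpha) * ((theta+alpha)^(n)/theta^(n) - 1), rearranged so every
  # lgamma argument is positive for theta in (-alpha, 0] as well
  r <- exp(lgamma(theta + alpha + n) - lgamma(theta + alpha + 1) -
             lgamma(theta + n) + lgamma(theta + 1))
  ((theta + alpha) * r - theta) / alpha
}

#' @rdname pitman_expected_classes
#' @keywords internal
pitman_expected_singletons <- function(theta, alpha, n) {
  if (n == 0) return(0)
  n * exp(lgamma(theta + alpha + n - 1) - lgamma(theta + alpha) -
            lgamma(theta + n) + lgamma(theta + 1))
}

# Solve E K_n(theta, alpha) = u for theta at fixed alpha (E is increasing in
# theta, from 1 at theta -> -alpha up to n). Returns NA if u is out of range.
pitman_theta_for_u <- function(alpha, n, u, tol = 1e-9, theta_max = 1e7) {
  f <- function(th) pitman_expected_classes(th, alpha, n) - u
  lo <- -alpha + 1e-10
  if (f(lo) > 0) return(NA_real_)
  hi <- max(1, -alpha + 1)
  while (f(hi) < 0 && hi < theta_max) hi <- hi * 4
  if (f(hi) < 0) return(theta_max)   # u ~ n: effectively all-singleton
  stats::uniroot(f, c(lo, hi), tol = tol, maxiter = 200L)$root
}

#' Fit the Pitman model to an equivalence-class histogram
#'
#' Method-of-moments fit of the two-parameter Poisson-Dirichlet model
#' PD(alpha, theta) to an observed class-size histogram: the parameters are
#' chosen so that the expected number of classes and the expected number of
#' singleton classes at the observed sample size match the observed counts
#' `u` and `u1` (a bivariate non-linear system). The search profiles out
#' theta — for each alpha in `[0, 1)` the class-count equation is solved for
#' theta by Brent root-finding (it is monotone in theta), and alpha is then
#' found by a one-dimensional root search on the singleton equation.
#' Residual tolerance 1e-9, at most 200 iterations per root.
#'
#' Degenerate histograms never raise an error (the lattice searches evaluate
#' thousands of candidate schemes and must not abort): when no root exists in
#' the box — including the all-singleton boundary (alpha -> 1) and histograms
#' without singletons — the fit falls back to alpha = 0 with theta matched to
#' the class count alone and is flagged `converged = FALSE`.
#'
#' @param sizes positive integer vector of equivalence-class sizes.
#' @return Object of class `"pitman_fit"`: list with `theta`, `alpha`,
#'   `converged`, `degenerate`, plus the observed `n`, `u`, `u1`.
#' @examples
#' fit_pitman(c(1, 1, 2, 3, 5, 1, 2))
#' @export
fit_pitman <- function(sizes) {
  sizes <- as.integer(sizes)
  if (length(sizes) == 0L || sum(sizes) < 1L)
    stop("cannot fit the Pitman model to an empty histogram")
  stopifnot(all(sizes >= 1L))
  n <- sum(sizes)
  u <- length(sizes)
  u1 <- sum(sizes == 1L)

  fallback <- function(degenerate) {
    theta <- pitman_theta_for_u(0, n, u)
    if (is.na(theta)) theta <- 1e-10
    structure(list(theta = theta, alpha = 0, converged = FALSE,
                   degenerate = degenerate, n = n, u = u, u1 = u1),
              class = "pitman_fit")
  }

  if (u1 == 0L || u == n || n == 1L)
    return(fallback(degenerate = TRUE))

  g <- function(alpha) {
    theta <- pitman_theta_for_u(alpha, n, u)
    if (is.na(theta)) return(NA_real_)
    pitman_expected_singletons(theta, alpha, n) - u1
  }
  # bracket a sign change of g on [0, 1): endpoints first, then a grid scan
  # (g need not be monotone; the boundary stays off 1 to keep the log-gamma
  # terms well conditioned)
  grid <- c(0, seq(0.05, 0.95, by = 0.05), 0.99, 1 - 1e-6)
  gv <- vapply(grid, g, numeric(1))
  ok <- !is.na(gv)
  sc <- which(ok[-length(ok)] & ok[-1] &
                gv[-length(gv)] * gv[-1] <= 0)
  if (length(sc) == 0L) return(fallback(FALSE))
  root <- stats::uniroot(g, grid[c(sc[1L], sc[1L] + 1L)],
                         f.lower = gv[sc[1L]], f.upper = gv[sc[1L] + 1L],
                         tol = 1e-9, maxiter = 200L)
  alpha <- root$root
  theta <- pitman_theta_for_u(alpha, n, u)
  structure(list(theta = theta, alpha = alpha,
                 converged = abs(root$f.root) < 1e-3 * max(1, u1),
                 degenerate = FALSE, n = n, u = u, u1 = u1),
            class = "pitman_fit")
}

#' @export
print.pitman_fit <- function(x, ...) {
  cat(sprintf("Pitman (Poisson-Dirichlet) fit: theta = %.4g, alpha = %.4g\n",
              x$theta, x$alpha))
  cat(sprintf("  sample: n = %d, classes = %d, singletons = %d\n",
              x$n, x$u, x$u1))
  if (x$degenerate) cat("  degenerate histogram; fallback fit (alpha = 0)\n")
  else if (!x$converged) cat("  moment equations not solved in the box;",
                             "fallback fit (alpha = 0)\n")
  invisible(x)
}

#' Estimate population uniqueness from a sample histogram
#'
#' Estimates the fraction of *population* records that are unique on the
#' quasi-identifiers, given the equivalence-class histogram of a sample drawn
#' with sampling fraction `pi`. The Pitman model is fitted to the sample
#' (see [fit_pitman()]) and extrapolated to the population size
#' `N = round(n / pi)`: the estimate is the expected number of singleton
#' classes at size `N`, divided by `N`.
#'
#' Two short-circuits are exact: `pi = 1` (the sample *is* the population)
#' returns `u1 / n`, and a histogram without singleton classes returns 0.
#'
#' @param sizes equivalence-class sizes of the sample (may be empty: returns
#'   0).
#' @param pi sampling fraction in `(0, 1]`.
#' @param fit optionally, a pre-computed [fit_pitman()] result for `sizes`.
#' @return Estimated fraction in `[0, 1]`.
#' @export
estimate_population_uniqueness <- function(sizes, pi, fit = NULL) {
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi > 1)
    stop("sampling fraction pi must lie in (0, 1]")
  if (length(sizes) == 0L) return(0)
  n <- sum(sizes)
  u1 <- sum(sizes == 1L)
  if (u1 == 0L) return(0)
  if (pi == 1) return(u1 / n)
  fit <- fit %||% fit_pitman(sizes)
  N <- round(n / pi)
  est <- pitman_expected_singletons(fit$theta, fit$alpha, N) / N
  min(max(est, 0), 1)
}
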