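#' Positive zeros of the first-order Bessel function J1
#'
#' Computes the first `n_roots` positive roots of \eqn{J_1(\alpha) = 0},
#' excluding the trivial root at 0. These are the radial eigenvalues of the
#' finite-bath cylindrical diffusion problem with a zero-flux outer boundary:
#' the eigenmodes are \eqn{J_0(\alpha_n r / b)} and the constant (equilibrium)
#' mode corresponding to \eqn{\alpha = 0} is carried analytically as the
#' plateau term of the release formula, so it is deliberately not part of the
#' basis.
#'
#' Each root is bracketed from the McMahon asymptotic approximation
#' \eqn{\alpha_n \approx (n + 1/4)\pi - 3/(8\beta)} (roots of \eqn{J_1} are
#' separated by close to \eqn{\pi}, so the brackets cannot capture a
#' neighbouring root), refined by [stats::uniroot()] at machine tolerance and
#' polished with two Newton steps using \eqn{J_1'(x) = J_0(x) - J_1(x)/x}.
#' The computation is deterministic: repeated calls return identical values.
#'
#' @param n_roots Number of roots to compute (positive integer). The default
#'   truncation used throughout the package is 62 terms.
#' @return An object of class `eigen_basis`: a list with components
#'   `roots` (strictly increasing positive numeric vector) and
#'   `truncation_order` (`= n_roots`).
#' @examples
#' b <- j1_roots(3)
#' b$roots          # 3.831706, 7.015587, 10.173468
#' besselJ(b$roots, 1)  # all ~ 0
#' @export
j1_roots <- function(n_roots = 62L) {
  if (length(n_roots) != 1L || !is.numeric(n_roots) || is.na(n_roots) ||
      n_roots < 1 || n_roots != round(n_roots)) {
    stop("'n_roots' must be a single positive integer", call. = FALSE)
  }
  n_roots <- as.integer(n_roots)
  beta <- (seq_len(n_roots) + 0.25) * pi
  approx <- beta - 3 / (8 * beta)
  roots <- vapply(approx, function(x0) {
    lo <- x0 - 0.4
    hi <- x0 + 0.4
    r <- stats::uniroot(function(x) besselJ(x, 1), c(lo, hi),
                        tol = .Machine$double.eps)$root
    # two Newton polishing steps for machine-precision, bit-stable roots
    for (i in 1:2) {
      f <- besselJ(r, 1)
      fp <- besselJ(r, 0) - f / r
      r <- r - f / fp
    }
    r
  }, numeric(1))
  structure(list(roots = roots, truncation_order = n_roots),
            class = "eigen_basis")
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat("Bessel J1 eigenbasis: ", x$truncation_order, " positive roots, ",
      sprintf("first %.6f, last %.6f\n", x$roots[1L],
              x$roots[x$truncation_order]))
  invisible(x)
}

#' Upper bound on the truncation error of the release series
#'
#' The cumulative-release series has positive terms
#' \eqn{c_n \exp(-\alpha_n^2 \tau / b^2)} with
#' \eqn{c_n = 4 [J_1(\alpha_n a/b) / (\alpha_n J_0(\alpha_n))]^2}.
#' This function bounds the tail neglected beyond the basis truncation order
#' at dimensionless diffusion time \eqn{s = \tau / b^2}.
#'
#' The bound uses the large-argument envelopes
#' \eqn{J_1(x)^2 \le 2/(\pi x)} and, at the zeros of \eqn{J_1},
#' \eqn{J_0(\alpha_n)^2 \ge 1/(\pi \alpha_n)} (the asymptotic value
#' \eqn{2/(\pi \alpha_n)} with an explicit safety factor of 2), giving
#' \eqn{c_n \le 8 b / (a\, \alpha_n^2)}. Roots beyond the cache are bounded
#' below by \eqn{(n + 1/4)\pi - 1/(2\beta)}; an integral remainder closes the
#' sum. The result is monotone non-increasing in `scaled_time` and in the
#' truncation order, and conservative (it exceeds the true tail).
#'
#' @param basis An [`eigen_basis`][j1_roots] giving the truncation order.
#' @param scaled_time Dimensionless time \eqn{\tau / b^2 \ge 0} (effective
#'   diffusion time over squared bath radius).
#' @param radius_ratio Device-to-bath radius ratio \eqn{a/b \in (0, 1)}.
#' @param n_tail_terms Number of explicit tail terms before the integral
#'   remainder takes over.
#' @return A non-negative scalar bounding the absolute neglected tail.
#' @export
tail_bound <- function(basis, scaled_time, radius_ratio, n_tail_terms = 400L) {
  stopifnot(inherits(basis, "eigen_basis"))
  if (length(scaled_time) != 1L || !is.finite(scaled_time) || scaled_time < 0) {
    stop("'scaled_time' must be a single non-negative number", call. = FALSE)
  }
  if (length(radius_ratio) != 1L || !is.finite(radius_ratio) ||
      radius_ratio <= 0 || radius_ratio >= 1) {
    stop("'radius_ratio' must be in (0, 1)", call. = FALSE)
  }
  N <- basis$truncation_order
  m <- (N + 1L):(N + n_tail_terms)
  beta <- (m + 0.25) * pi
  a_lo <- beta - 0.5 / beta  # guaranteed below the true root
  terms <- (8 / radius_ratio) / a_lo^2 * exp(-a_lo^2 * scaled_time)
  # integral remainder beyond the last explicit term, with the slowest
  # exponential factor pulled out
  M <- N + n_tail_terms
  rem <- (8 / radius_ratio) / (pi^2 * M) * exp(-a_lo[n_tail_terms]^2 * scaled_time)
  sum(terms) + rem
}
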