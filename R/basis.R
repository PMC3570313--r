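#' B-spline basis system for OGTT curves
#'
#' Builds the B-spline basis used throughout the package: a knot at each
#' sampling time (boundary knots repeated to multiplicity `order`), the
#' Gram matrix of pairwise basis inner products over the time domain, and
#' the roughness-penalty matrix of inner products of second derivatives.
#' With the canonical five breakpoints and cubic splines (`order = 4`) the
#' basis has K = 3 interior knots + 4 = 7 functions.
#'
#' Both matrices are computed by Gauss--Legendre quadrature per knot
#' interval with enough nodes to be exact for the piecewise-polynomial
#' integrands.
#'
#' @param breakpoints Strictly increasing sampling times in minutes.
#' @param order Spline order (polynomial degree + 1); default 4 (cubic).
#' @return An object of class `ogtt_basis`: a list with elements
#'   `order`, `breakpoints`, `knots` (full knot vector), `K` (number of
#'   basis functions), `W` (K x K Gram matrix), `R` (K x K roughness
#'   penalty), and `int_phi` (K-vector of basis integrals, used for sign
#'   orientation of eigenfunctions).
#' @examples
#' b <- ogtt_basis()
#' b$K                                   # 7
#' range(rowSums(eval_basis(b, 0:120)))  # partition of unity
#' @export
ogtt_basis <- function(breakpoints = ogtt_times(), order = 4L) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) < 2L || anyDuplicated(breakpoints) ||
      is.unsorted(breakpoints, strictly = TRUE))
    stop("'breakpoints' must be >= 2 strictly increasing distinct values")
  if (order < 2L) stop("'order' must be >= 2")
  order <- as.integer(order)

  lo <- breakpoints[1L]; hi <- breakpoints[length(breakpoints)]
  knots <- c(rep(lo, order), breakpoints[-c(1L, length(breakpoints))],
             rep(hi, order))
  K <- length(knots) - order

  # quadrature exact for products of two order-`order` pieces (degree
  # 2*(order-1) <= 2*nq - 1)
  nq <- order + 1L
  W <- matrix(0, K, K)
  R <- matrix(0, K, K)
  int_phi <- numeric(K)
  for (j in seq_len(length(breakpoints) - 1L)) {
    gl <- pracma::gaussLegendre(nq, breakpoints[j], breakpoints[j + 1L])
    B0 <- spline_design(knots, gl$x, order, deriv = 0L)
    W <- W + crossprod(B0 * sqrt(gl$w))
    int_phi <- int_phi + colSums(B0 * gl$w)
    if (order >= 3L) {
      B2 <- spline_design(knots, gl$x, order, deriv = 2L)
      R <- R + crossprod(B2 * sqrt(gl$w))
    }
  }
  W <- (W + t(W)) / 2
  R <- (R + t(R)) / 2

  structure(list(order = order, breakpoints = breakpoints, knots = knots,
                 K = K, W = W, R = R, int_phi = int_phi),
            class = "ogtt_basis")
}

# splineDesign wrapper handling the right boundary for derivatives
spline_design <- function(knots, x, order, deriv = 0L) {
  splines::splineDesign(knots, x, ord = order,
                        derivs = rep(deriv, length(x)))
}

#' Evaluate the basis functions
#'
#' @param basis An [ogtt_basis()] object.
#' @param t Evaluation times within the basis domain.
#' @param deriv Derivative order (0, 1 or 2).
#' @return A `length(t)` x K matrix of basis (derivative) values.
#' @export
eval_basis <- function(basis, t, deriv = 0L) {
  stopifnot(inherits(basis, "ogtt_basis"))
  rng <- range(basis$breakpoints)
  if (any(t < rng[1L] | t > rng[2L]))
    stop("evaluation times must lie within [", rng[1L], ", ", rng[2L], "]")
  spline_design(basis$knots, t, basis$order, deriv = as.integer(deriv))
}

#' @export
print.ogtt_basis <- function(x, ...) {
  cat("B-spline basis: order", x$order, "with", x$K, "functions on [",
      x$breakpoints[1L], ",", x$breakpoints[length(x$breakpoints)], "]\n")
  cat("breakpoints:", paste(x$breakpoints, collapse = ", "), "\n")
  invisible(x)
}
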