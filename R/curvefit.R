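#' Penalized B-spline smoothing of OGTT measurements
#'
#' Fits each subject's measurements with a linear combination of B-spline
#' basis functions by penalized least squares,
#' minimising \eqn{(Y - \Phi C)^T (Y - \Phi C) + \lambda C^T R C}
#' where \eqn{R} penalises total squared curvature (integrated squared
#' second derivative). The closed-form solution
#' \eqn{C = (\Phi^T\Phi + \lambda R)^{-1} \Phi^T Y} is computed via a
#' Cholesky decomposition shared by all subjects (all subjects share the
#' same design).
#'
#' With more basis functions than sampling times (K = 7 > J = 5 by
#' default) the unpenalized system is singular, so `lambda` must be
#' positive unless K <= J.
#'
#' @param Y Numeric J x n matrix: one row per breakpoint (sampling time),
#'   one column per subject. No missing cells.
#' @param basis An [ogtt_basis()] object whose breakpoints match the rows
#'   of `Y`.
#' @param lambda Smoothing parameter, a single non-negative number shared
#'   by all subjects, or a length-n vector for per-subject smoothing.
#' @return An object of class `ogtt_curvefit`: a list with `basis`,
#'   `coefficients` (K x n), `lambda`, `dof` (effective degrees of freedom
#'   = trace of the hat matrix), `gcv` (pooled generalized cross-validation
#'   score), `fitted` (J x n fitted values at the breakpoints), `sse`
#'   (per-subject residual sum of squares) and `Y`.
#' @seealso [select_lambda_gcv()] to choose `lambda`,
#'   [predict.ogtt_curvefit()] to evaluate the curves.
#' @examples
#' b <- ogtt_basis()
#' Y <- matrix(c(4.0, 5.7, 5.0, 4.5, 4.1), 5, 3)  # three identical subjects
#' fit <- fit_ogtt_curves(Y, b, lambda = 1)
#' fit$dof
#' @export
fit_ogtt_curves <- function(Y, basis, lambda) {
  stopifnot(inherits(basis, "ogtt_basis"))
  Y <- as.matrix(Y)
  J <- length(basis$breakpoints)
  if (nrow(Y) != J)
    stop("'Y' must have one row per breakpoint (", J, " rows)")
  if (anyNA(Y) || any(!is.finite(Y)))
    stop("'Y' must not contain missing or non-finite values; ",
         "use filter_complete() first")
  n <- ncol(Y)
  if (!(length(lambda) %in% c(1L, n)) || any(!is.finite(lambda)) ||
      any(lambda < 0))
    stop("'lambda' must be a finite non-negative scalar or length-n vector")

  Phi <- eval_basis(basis, basis$breakpoints)
  if (length(lambda) == 1L) {
    sol <- penalized_solve(Phi, basis$R, lambda, Y)
    C <- sol$C; dof <- sol$dof
  } else {
    C <- matrix(0, basis$K, n)
    dof <- numeric(n)
    for (lam in unique(lambda)) {
      idx <- which(lambda == lam)
      sol <- penalized_solve(Phi, basis$R, lam, Y[, idx, drop = FALSE])
      C[, idx] <- sol$C
      dof[idx] <- sol$dof
    }
  }
  fitted <- Phi %*% C
  sse <- colSums((Y - fitted)^2)
  gcv <- sum(J * sse / (J - dof)^2)

  structure(list(basis = basis, coefficients = C, lambda = lambda,
                 dof = if (length(lambda) == 1L) dof[1L] else dof,
                 gcv = gcv, fitted = fitted, sse = sse, Y = Y,
                 n = n),
            class = "ogtt_curvefit")
}

# solve min ||Y - Phi C||^2 + lambda C'RC via the augmented least-squares
# system [Phi; sqrt(lambda) L] with L'L = R, using QR — numerically stable
# for both tiny and huge lambda (the normal equations square the condition
# number). Returns coefficients and the effective degrees of freedom
# trace(Phi (Phi'Phi + lambda R)^{-1} Phi').
penalized_solve <- function(Phi, R, lambda, Y) {
  J <- nrow(Phi); K <- ncol(Phi)
  eR <- eigen((R + t(R)) / 2, symmetric = TRUE)
  pos <- eR$values > max(eR$values, 0) * 1e-12
  L <- sqrt(pmax(eR$values[pos], 0)) * t(eR$vectors[, pos, drop = FALSE])
  X <- rbind(Phi, sqrt(lambda) * L)
  qx <- qr(X)
  if (qx$rank < K)
    stop("penalized system is singular: with more basis functions than ",
         "time points a positive 'lambda' is required")
  pad <- matrix(0, nrow(L), ncol(Y))
  C <- qr.coef(qx, rbind(Y, pad))
  Ainv_PhiT <- qr.coef(qx, rbind(diag(J), matrix(0, nrow(L), J)))
  dof <- rep(sum(Phi * t(Ainv_PhiT)), ncol(Y))
  list(C = C, dof = dof)
}

#' Choose the smoothing parameter by generalized cross-validation
#'
#' Evaluates the pooled GCV criterion
#' \eqn{GCV(\lambda) = \sum_i J \, SSE_i(\lambda) / (J - df(\lambda))^2}
#' on a log-spaced grid and refines the minimum by golden-section search
#' between the neighbouring grid points. All subjects share one lambda by
#' default (identical designs make per-curve GCV unstable at J = 5); a
#' per-curve mode is available.
#'
#' Grid points where the effective degrees of freedom reach J (so the
#' smoother interpolates and the GCV denominator vanishes) are skipped
#' with a warning.
#'
#' @param Y J x n measurement matrix as in [fit_ogtt_curves()].
#' @param basis An [ogtt_basis()] object.
#' @param grid Positive candidate lambdas; default 25 log-spaced points in
#'   \[1e-4, 1e4\].
#' @param mode `"shared"` (one lambda for all subjects, pooled GCV) or
#'   `"per_curve"` (one lambda per subject).
#' @return A list with `lambda` (the minimizer; vector in per-curve mode),
#'   `gcv` (criterion at the minimizer), `grid` and `gcv_grid` (the
#'   criterion along the grid; matrix in per-curve mode).
#' @export
select_lambda_gcv <- function(Y, basis,
                              grid = 10^seq(-4, 4, length.out = 25),
                              mode = c("shared", "per_curve")) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  if (length(grid) < 1L || any(grid <= 0))
    stop("'grid' must be non-empty with positive values")
  grid <- sort(grid)
  J <- length(basis$breakpoints)

  gcv_of <- function(lam, cols = NULL) {
    Ysub <- if (is.null(cols)) Y else Y[, cols, drop = FALSE]
    fit <- fit_ogtt_curves(Ysub, basis, lam)
    d <- fit$dof[1L]
    if (d >= J - 1e-8)
      return(rep(NA_real_, if (is.null(cols)) 1L else ncol(Ysub)))
    if (is.null(cols)) fit$gcv else J * fit$sse / (J - d)^2
  }

  if (mode == "shared") {
    vals <- vapply(grid, gcv_of, numeric(1L))
    if (anyNA(vals))
      warning(sum(is.na(vals)), " grid point(s) skipped: ",
              "effective df >= number of time points")
    if (all(is.na(vals))) stop("GCV undefined on the whole grid")
    i <- which.min(vals)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    lam <- golden_section(function(l) {
      v <- gcv_of(l); if (is.na(v)) Inf else v
    }, log(lo), log(hi))
    lam <- exp(lam)
    list(lambda = lam, gcv = gcv_of(lam), grid = grid, gcv_grid = vals)
  } else {
    n <- ncol(Y)
    M <- vapply(grid, function(l) gcv_of(l, seq_len(n)), numeric(n))
    M <- matrix(M, nrow = n)   # n x |grid|
    lambda <- numeric(n)
    for (s in seq_len(n)) {
      vals <- M[s, ]
      i <- which.min(vals)
      lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
      lambda[s] <- exp(golden_section(function(l) {
        v <- gcv_of(l, s); if (is.na(v)) Inf else v
      }, log(lo), log(hi)))
    }
    list(lambda = lambda, gcv = NA_real_, grid = grid, gcv_grid = M)
  }
}

# golden-section minimisation on [a, b]; f evaluated at exp-scale by caller
golden_section <- function(f, a, b, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(exp(x1)); f2 <- f(exp(x2))
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(exp(x1))
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(exp(x2))
    }
  }
  (a + b) / 2
}

#' Evaluate fitted OGTT curves on a time grid
#'
#' @param object An `ogtt_curvefit` object.
#' @param t Evaluation times in minutes within the domain; default a
#'   1-minute grid.
#' @param deriv Derivative order.
#' @param ... Unused.
#' @return A `length(t)` x n matrix of curve values (one column per
#'   subject).
#' @export
predict.ogtt_curvefit <- function(object, t = seq(0, 120), deriv = 0L, ...) {
  eval_basis(object$basis, t, deriv) %*% object$coefficients
}

#' @export
fitted.ogtt_curvefit <- function(object, ...) object$fitted

#' @export
residuals.ogtt_curvefit <- function(object, ...) object$Y - object$fitted

#' @export
print.ogtt_curvefit <- function(x, ...) {
  cat("Penalized B-spline fit:", x$n, "curves, K =", x$basis$K, "\n")
  if (length(x$lambda) == 1L) {
    cat(sprintf("lambda = %.6g, effective df = %.3f, pooled GCV = %.6g\n",
                x$lambda, x$dof, x$gcv))
  } else {
    cat(sprintf("per-curve lambda in [%.3g, %.3g]\n",
                min(x$lambda), max(x$lambda)))
  }
  invisible(x)
}

#' Integrated squared second derivative of each fitted curve
#'
#' @param fit An `ogtt_curvefit` object.
#' @return Per-subject roughness \eqn{c_i^T R c_i}.
#' @export
curve_roughness <- function(fit) {
  colSums(fit$coefficients * (fit$basis$R %*% fit$coefficients))
}
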