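#' Functional principal component analysis of fitted OGTT curves
#'
#' Extracts the dominant modes of between-subject variation from a set of
#' fitted curves. Each eigenfunction \eqn{\xi_\kappa(t)} maximises the
#' variance of the subject scores
#' \eqn{z_{\kappa i} = \int \xi_\kappa(t) (x_i(t) - \mu(t)) dt}
#' subject to \eqn{\int \xi_\kappa^2 = 1} and orthogonality to the earlier
#' eigenfunctions. Scores are computed on curves centred at the sample
#' mean curve, so a subject at the mean scores zero on every component.
#'
#' The eigenproblem is solved exactly in coefficient space: with Gram
#' matrix W and centred coefficient covariance \eqn{\Sigma_c}, the
#' eigenvectors of \eqn{W^{1/2} \Sigma_c W^{1/2}} map back to
#' eigenfunction coefficients through \eqn{W^{-1/2}}.
#'
#' Signs are canonicalized: each eigenfunction is oriented so its time
#' integral is positive; if that integral is numerically zero, so that the
#' function's end-minus-start difference is positive; failing that, so its
#' value at the left endpoint is positive. Under this convention the first
#' component of a typical OGTT sample is a level shift (high score = high
#' overall glucose).
#'
#' @param fit An [fit_ogtt_curves()] result with at least two curves.
#' @param n_components Number of leading components retained for
#'   downstream analyses (all K are computed and stored); default 3.
#' @return An object of class `ogtt_fpca`: a list with
#'   `mean_coefficients` (K-vector of the mean curve),
#'   `eigenfunction_coefficients` (K x K, leading components first),
#'   `eigenvalues` (descending, = score variances), `variance_proportions`,
#'   `scores` (n x K, centred), `n_components`, and `basis`.
#' @examples
#' coh <- simulate_ogtt_cohort(50, seed = 1, missing_fraction = 0)
#' fit <- fit_ogtt_curves(cohort_matrix(coh), ogtt_basis(), lambda = 1)
#' pca <- ogtt_fpca(fit)
#' summary(pca)
#' @export
ogtt_fpca <- function(fit, n_components = 3L) {
  stopifnot(inherits(fit, "ogtt_curvefit"))
  C <- fit$coefficients
  n <- ncol(C); K <- nrow(C)
  if (n < 2L) stop("FPCA needs at least 2 curves")
  if (n_components > K)
    stop("'n_components' cannot exceed the basis dimension K = ", K)

  W <- fit$basis$W
  eW <- eigen(W, symmetric = TRUE)
  W_half <- eW$vectors %*% (sqrt(eW$values) * t(eW$vectors))
  W_half_inv <- eW$vectors %*% ((1 / sqrt(eW$values)) * t(eW$vectors))

  mu <- rowMeans(C)
  Cc <- C - mu
  Sigma_c <- tcrossprod(Cc) / (n - 1)
  M <- W_half %*% Sigma_c %*% W_half
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  evals <- pmax(eM$values, 0)
  B <- W_half_inv %*% eM$vectors          # eigenfunction coefficients
  Z <- crossprod(Cc, W %*% B)             # n x K centred scores

  # canonical sign orientation
  for (k in seq_len(K)) {
    b <- B[, k]
    s <- sum(b * fit$basis$int_phi)
    nrm <- sqrt(sum(b * (W %*% b)))
    if (abs(s) >= 1e-6 * nrm) {
      flip <- s < 0
    } else {
      ends <- drop(eval_basis(fit$basis, range(fit$basis$breakpoints)) %*% b)
      d <- ends[2L] - ends[1L]
      flip <- if (abs(d) >= 1e-8) d < 0 else ends[1L] < 0
    }
    if (flip) { B[, k] <- -b; Z[, k] <- -Z[, k] }
  }

  total <- sum(evals)
  props <- if (total > 0) evals / total else rep(0, K)

  structure(list(mean_coefficients = mu,
                 eigenfunction_coefficients = B,
                 eigenvalues = evals,
                 variance_proportions = props,
                 scores = Z,
                 n_components = as.integer(n_components),
                 basis = fit$basis, n = n),
            class = "ogtt_fpca")
}

#' Scores of (possibly new) curves on fitted components
#'
#' Projects curves onto the eigenfunctions of an existing FPCA, centring
#' at the FPCA's mean curve:
#' \eqn{z_{\kappa i} = \int \xi_\kappa(t)(x_i(t) - \mu(t)) dt}.
#'
#' @param object An `ogtt_fpca` object.
#' @param fit An `ogtt_curvefit` on the same basis.
#' @param n_components Number of score columns; default the FPCA's
#'   retained components.
#' @return n x m score matrix.
#' @export
fpca_scores <- function(object, fit, n_components = object$n_components) {
  stopifnot(inherits(object, "ogtt_fpca"), inherits(fit, "ogtt_curvefit"))
  if (!isTRUE(all.equal(object$basis$knots, fit$basis$knots)) ||
      object$basis$order != fit$basis$order)
    stop("FPCA and curve fit use different basis systems")
  Cc <- fit$coefficients - object$mean_coefficients
  m <- n_components
  crossprod(Cc, object$basis$W %*%
              object$eigenfunction_coefficients[, seq_len(m), drop = FALSE])
}

#' Variance decomposition table
#'
#' @param object An `ogtt_fpca` object.
#' @param ... Unused.
#' @return A data frame with one row per component: eigenvalue (score
#'   variance), proportion of total between-curve variance, and cumulative
#'   proportion.
#' @export
summary.ogtt_fpca <- function(object, ...) {
  data.frame(component = seq_along(object$eigenvalues),
             eigenvalue = object$eigenvalues,
             proportion = object$variance_proportions,
             cumulative = cumsum(object$variance_proportions))
}

#' Mode-of-variation curves
#'
#' The standard visualisation of a functional principal component: the
#' mean curve plus and minus `multiple` score standard deviations times
#' the eigenfunction, showing what a high or low score means.
#'
#' @param object An `ogtt_fpca` object.
#' @param component Component index.
#' @param multiple Number of score SDs; default 1.
#' @param t Evaluation grid in minutes.
#' @return A data frame with columns `t`, `mean`, `plus`, `minus`.
#' @export
mode_curves <- function(object, component = 1L, multiple = 1,
                        t = seq(0, 120)) {
  stopifnot(inherits(object, "ogtt_fpca"))
  if (component > ncol(object$eigenfunction_coefficients))
    stop("component out of range")
  Phi <- eval_basis(object$basis, t)
  mu <- drop(Phi %*% object$mean_coefficients)
  xi <- drop(Phi %*% object$eigenfunction_coefficients[, component])
  off <- multiple * sqrt(object$eigenvalues[component]) * xi
  data.frame(t = t, mean = mu, plus = mu + off, minus = mu - off)
}

#' Quartile panel assignment for score scatter displays
#'
#' Cross-classifies subjects by the lower and upper quartiles of two score
#' columns into a 3 x 3 grid of panels (below Q1 / middle / above Q3 on
#' each axis).
#'
#' @param scores Score matrix (subjects x components).
#' @param components Two component indices; default first and second.
#' @return A data frame with the two tercile-like classifications
#'   (`"Q1"`, `"mid"`, `"Q3"`) and a combined `panel` factor with 9
#'   levels.
#' @export
quartile_panels <- function(scores, components = c(1L, 2L)) {
  s1 <- scores[, components[1L]]; s2 <- scores[, components[2L]]
  cls <- function(x) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    factor(ifelse(x < q[1L], "Q1", ifelse(x > q[2L], "Q3", "mid")),
           levels = c("Q1", "mid", "Q3"))
  }
  a <- cls(s1); b <- cls(s2)
  data.frame(band1 = a, band2 = b,
             panel = interaction(a, b, sep = "/", lex.order = TRUE))
}

#' @export
print.ogtt_fpca <- function(x, ...) {
  m <- x$n_components
  cat("Functional PCA of", x$n, "curves (", m, "components retained )\n")
  tab <- summary(x)[seq_len(m), ]
  cat(sprintf("  FPC%d: %5.1f%% of variance (cumulative %5.1f%%)\n",
              tab$component, 100 * tab$proportion, 100 * tab$cumulative),
      sep = "")
  invisible(x)
}
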