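# Independent oracles used across the suite. These deliberately avoid the
# package's own linear-algebra path.

# Cox-de Boor recursion for a single B-spline basis function
deboor_basis <- function(knots, i, ord, x) {
  if (ord == 1L)
    return(as.numeric(knots[i] <= x &
                        (x < knots[i + 1L] |
                           (x == knots[i + 1L] &
                              knots[i + 1L] == knots[length(knots)]))))
  d1 <- knots[i + ord - 1L] - knots[i]
  d2 <- knots[i + ord] - knots[i + 1L]
  a <- if (d1 > 0) (x - knots[i]) / d1 * deboor_basis(knots, i, ord - 1L, x) else 0
  b <- if (d2 > 0) (knots[i + ord] - x) / d2 *
    deboor_basis(knots, i + 1L, ord - 1L, x) else 0
  a + b
}

deboor_design <- function(knots, x, ord) {
  K <- length(knots) - ord
  vapply(seq_len(K), function(i) deboor_basis(knots, i, ord, x),
         numeric(length(x)))
}

# trapezoid weights on a uniform grid
trap_weights <- function(grid) {
  h <- diff(grid)
  w <- numeric(length(grid))
  w[-length(w)] <- w[-length(w)] + h / 2
  w[-1L] <- w[-1L] + h / 2
  w
}

# Simpson weights on a uniform grid with an even number of intervals
simpson_weights <- function(grid) {
  m <- length(grid)
  stopifnot(m %% 2L == 1L)
  h <- grid[2L] - grid[1L]
  w <- rep(c(2, 4), length.out = m)
  w[c(1L, m)] <- 1
  w * h / 3
}

# brute-force functional PCA by quadrature on a dense grid:
# curves X (grid x n), returns eigenvalues, eigenfunctions on the grid,
# and centred scores
grid_pca <- function(X, grid) {
  n <- ncol(X)
  w <- simpson_weights(grid)
  Xc <- X - rowMeans(X)
  Kcov <- tcrossprod(Xc) / (n - 1)            # covariance on the grid
  sw <- sqrt(w)
  M <- (sw %o% sw) * Kcov
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  xi <- e$vectors / sw                         # back to function values
  scores <- t(Xc * w) %*% xi
  list(values = pmax(e$values, 0), functions = xi, scores = scores)
}

# multinomial logit log-likelihood and gradient for reference-coded
# parameters; y integer in 1..L (1 = reference), X design WITH intercept,
# theta is a (L-1) x p matrix flattened row-wise
mlogit_loglik <- function(theta, y, X, L) {
  p <- ncol(X)
  Th <- matrix(theta, L - 1L, p)
  eta <- cbind(0, X %*% t(Th))
  eta <- eta - apply(eta, 1L, max)
  sum(eta[cbind(seq_along(y), y)] - log(rowSums(exp(eta))))
}

mlogit_grad <- function(theta, y, X, L) {
  p <- ncol(X)
  Th <- matrix(theta, L - 1L, p)
  eta <- cbind(0, X %*% t(Th))
  eta <- eta - apply(eta, 1L, max)
  P <- exp(eta) / rowSums(exp(eta))
  G <- matrix(0, L - 1L, p)
  for (k in 2:L) {
    r <- (y == k) - P[, k]
    G[k - 1L, ] <- colSums(r * X)
  }
  as.numeric(G)
}

# small deterministic complete cohort for I/O tests
toy_cohort <- function(n = 6L) {
  set.seed(99)
  simulate_ogtt_cohort(n, missing_fraction = 0, seed = 99)
}
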