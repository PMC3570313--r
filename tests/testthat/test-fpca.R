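basis <- ogtt_basis()

fit_from_coh <- function(n, seed, lambda = 50, ...) {
  coh <- simulate_ogtt_cohort(n, seed = seed, missing_fraction = 0, ...)
  fit_ogtt_curves(cohort_matrix(coh), basis, lambda)
}

test_that("degenerate samples: identical curves and a rank-1 pair", {
  Y <- matrix(c(4.0, 5.7, 5.0, 4.5, 4.1), 5, 6)
  pca <- ogtt_fpca(fit_ogtt_curves(Y, basis, 1))
  expect_lt(max(pca$eigenvalues), 1e-10)

  # two-curve sample {mu + delta, mu - delta}: one nonzero eigenvalue,
  # first eigenfunction proportional to delta
  delta <- c(0.5, 0.3, -0.2, 0.1, 0.4)
  Y2 <- cbind(c(4.0, 5.7, 5.0, 4.5, 4.1) + delta,
              c(4.0, 5.7, 5.0, 4.5, 4.1) - delta)
  fit2 <- fit_ogtt_curves(Y2, basis, 1e-6)
  pca2 <- ogtt_fpca(fit2)
  expect_gt(pca2$eigenvalues[1L], 0)
  expect_lt(pca2$eigenvalues[2L] / pca2$eigenvalues[1L], 1e-10)
  expect_equal(pca2$variance_proportions[1L], 1, tolerance = 1e-8)
  # cosine similarity between xi1 and the (smoothed) delta curve
  grid <- seq(0, 120)
  xi1 <- drop(eval_basis(basis, grid) %*%
                pca2$eigenfunction_coefficients[, 1L])
  dcurve <- drop(eval_basis(basis, grid) %*%
                   (fit2$coefficients[, 1L] - fit2$coefficients[, 2L]) / 2)
  cosim <- abs(sum(xi1 * dcurve)) / sqrt(sum(xi1^2) * sum(dcurve^2))
  expect_gte(cosim, 1 - 1e-8)
})

test_that("orthonormality, score variance and conservation invariants", {
  fit <- fit_from_coh(80, seed = 14)
  pca <- ogtt_fpca(fit)
  B <- pca$eigenfunction_coefficients
  Winner <- t(B) %*% basis$W %*% B     # L2 inner products of eigenfunctions
  expect_lt(max(abs(Winner - diag(basis$K))), 1e-8)
  # score variance equals eigenvalue
  v <- apply(pca$scores, 2L, var)
  expect_equal(v, pca$eigenvalues, tolerance = 1e-6)
  # eigenvalues descending, proportions sum to one
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
  expect_equal(sum(pca$variance_proportions), 1, tolerance = 1e-8)
  # total variance conservation against dense-grid quadrature of Var[x(t)]
  grid <- seq(0, 120, by = 0.1)
  X <- predict(fit, grid)
  vart <- apply(X, 1L, var)
  expect_equal(sum(pca$eigenvalues), sum(trap_weights(grid) * vart),
               tolerance = 1e-4)
  # score columns mutually uncorrelated
  cc <- cor(pca$scores[, 1:3])
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
})

test_that("basis-space FPCA agrees with the dense-grid quadrature oracle", {
  fit <- fit_from_coh(40, seed = 15)
  pca <- ogtt_fpca(fit)
  grid <- seq(0, 120, by = 0.1)
  oracle <- grid_pca(predict(fit, grid), grid)
  m <- 4L
  expect_equal(pca$eigenvalues[1:m], oracle$values[1:m], tolerance = 1e-6)
  Phi <- eval_basis(basis, grid)
  for (k in seq_len(m)) {
    xi <- drop(Phi %*% pca$eigenfunction_coefficients[, k])
    cs <- sum(simpson_weights(grid) * xi * oracle$functions[, k])
    expect_equal(abs(cs), 1, tolerance = 1e-6)
    expect_equal(pca$scores[, k], sign(cs) * oracle$scores[, k],
                 tolerance = 1e-5)
  }
})

test_that("scores: mean curve scores zero; adding c*xi moves one score", {
  fit <- fit_from_coh(30, seed = 16)
  pca <- ogtt_fpca(fit)
  # the mean curve itself scores zero everywhere
  fit_mean <- fit
  fit_mean$coefficients <- matrix(pca$mean_coefficients, basis$K, 2)
  z <- fpca_scores(pca, fit_mean)
  expect_lt(max(abs(z)), 1e-8)
  # adding c * xi_2 to one curve raises its 2-score by c, others unmoved
  cshift <- 1.7
  fit2 <- fit
  fit2$coefficients[, 5L] <- fit$coefficients[, 5L] +
    cshift * pca$eigenfunction_coefficients[, 2L]
  z0 <- fpca_scores(pca, fit, n_components = 4L)
  z1 <- fpca_scores(pca, fit2, n_components = 4L)
  expect_equal(unname(z1[5L, 2L] - z0[5L, 2L]), cshift, tolerance = 1e-8)
  expect_lt(max(abs((z1 - z0)[, -2L])), 1e-8)
  expect_error(fpca_scores(pca, fit_ogtt_curves(fit$Y, ogtt_basis(order = 5L),
                                                1)), "different basis")
})

test_that("noiseless three-mode curves are recovered exactly in structure", {
  coh <- simulate_ogtt_cohort(1000, seed = 17, noise_sd = 0,
                              missing_fraction = 0, bmi_shifts = rep(0, 4))
  # near-interpolating fit so the curves carry the generating modes
  fit <- fit_ogtt_curves(cohort_matrix(coh), basis, 1e-6)
  pca <- ogtt_fpca(fit)
  grid <- seq(0, 120)
  w <- trap_weights(grid)
  Phi <- eval_basis(basis, grid)
  modes <- default_modes()
  for (k in 1:3) {
    xi <- drop(Phi %*% pca$eigenfunction_coefficients[, k])
    mk <- modes[[k]](grid)
    cosim <- abs(sum(w * xi * mk)) /
      sqrt(sum(w * xi^2) * sum(w * mk^2))
    expect_gte(cosim, 0.99)
  }
  shares <- pca$variance_proportions[1:3]
  truth <- c(6.0, 1.87, 0.99)^2 / sum(c(6.0, 1.87, 0.99)^2)
  expect_lt(max(abs(shares - truth)), 0.02)
  # sign convention: component 1 is an upward level shift
  xi1 <- drop(Phi %*% pca$eigenfunction_coefficients[, 1L])
  expect_true(all(xi1 > 0))
})

test_that("score SDs recover the generator inputs (noise-free cohort)", {
  # measurement noise systematically inflates the smallest component's
  # score SD, so the pure recovery property is checked noise-free; the
  # noisy-cohort variance shares are covered by the +/-0.02 check above
  coh <- simulate_ogtt_cohort(1000, seed = 18, missing_fraction = 0,
                              noise_sd = 0, bmi_shifts = rep(0, 4))
  Y <- cohort_matrix(coh)
  fit <- fit_ogtt_curves(Y, basis, select_lambda_gcv(Y, basis)$lambda)
  pca <- ogtt_fpca(fit)
  sds <- apply(pca$scores[, 1:3], 2L, sd)
  # components 1-2 (constant, ramp) lie in the spline space: direct
  # recovery of the generating SDs within Monte-Carlo tolerance
  expect_lt(max(abs(sds[1:2] - c(6.0, 1.87)) / c(6.0, 1.87)), 0.05)
  # the cosine mode is not in the 5-knot spline space; sampling at J = 5
  # and refitting replaces it by its roughness-minimising interpolant —
  # the natural cubic spline through the five cosine values — so the
  # recoverable score SD shrinks by that interpolant's L2 norm
  dense <- seq(0, 120, by = 0.01)
  mode3 <- default_modes()[[3L]]
  nat <- splinefun(ogtt_times(), mode3(ogtt_times()), method = "natural")
  atten <- sqrt(sum(trap_weights(dense) * nat(dense)^2))
  expect_lt(atten, 1)
  expect_equal(unname(sds[3L]), 0.99 * atten, tolerance = 0.05)
})

test_that("mode-of-variation curves are symmetric about the mean", {
  fit <- fit_from_coh(50, seed = 19)
  pca <- ogtt_fpca(fit)
  mc0 <- mode_curves(pca, 1L, multiple = 0)
  expect_equal(mc0$plus, mc0$mean, tolerance = 1e-12)
  expect_equal(mc0$minus, mc0$mean, tolerance = 1e-12)
  mc <- mode_curves(pca, 2L, multiple = 1.5)
  expect_equal(mc$plus - mc$mean, mc$mean - mc$minus, tolerance = 1e-12)
  # component 1 of the default generator is a near-uniform level shift
  # (checked at the default cohort size where the estimate is stable)
  pca1k <- ogtt_fpca(fit_from_coh(1000, seed = 23))
  mc1 <- mode_curves(pca1k, 1L)
  off <- mc1$plus - mc1$mean
  expect_lt(max(off) / min(off), 1.2)
})

test_that("quartile panels partition subjects into the 3x3 grid", {
  fit <- fit_from_coh(200, seed = 20)
  pca <- ogtt_fpca(fit)
  qp <- quartile_panels(pca$scores)
  expect_equal(nrow(qp), 200L)
  expect_false(anyNA(qp$panel))
  expect_equal(nlevels(qp$panel), 9L)
  # roughly half of subjects in each middle band
  expect_equal(mean(qp$band1 == "mid"), 0.5, tolerance = 0.05)
})

test_that("dimension and sample-size guards", {
  fit <- fit_from_coh(5, seed = 22)
  expect_error(ogtt_fpca(fit, n_components = 8L), "exceed")
  one <- subset(as.data.frame(simulate_ogtt_cohort(1, seed = 1,
                                                   missing_fraction = 0)),
                TRUE)
  f1 <- fit_ogtt_curves(cohort_matrix(ogtt_cohort(one)), basis, 1)
  expect_error(ogtt_fpca(f1), "at least 2")
})
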