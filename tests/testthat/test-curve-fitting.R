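basis <- ogtt_basis()

test_that("basis dimensions, partition of unity and penalty null space", {
  expect_equal(basis$K, 7L)           # 3 interior knots + order 4
  tt <- seq(0, 120, by = 0.5)
  expect_lt(max(abs(rowSums(eval_basis(basis, tt)) - 1)), 1e-10)
  # coefficients of the constant 4.0 have zero roughness
  Phi <- eval_basis(basis, seq(0, 120, by = 10))
  cc <- qr.solve(Phi, rep(4, nrow(Phi)))
  expect_lt(abs(drop(t(cc) %*% basis$R %*% cc)), 1e-10)
  # W symmetric positive definite, R positive semi-definite
  expect_true(all(eigen(basis$W, symmetric = TRUE)$values > 0))
  expect_true(all(eigen(basis$R, symmetric = TRUE)$values > -1e-10))
  expect_error(ogtt_basis(c(0, 30, 30, 120)), "increasing")
})

test_that("basis evaluation matches the Cox-de Boor recursion", {
  tt <- c(0, 0.5, 17.3, 30, 59.99, 60, 93.7, 119.5, 120)
  expect_lt(max(abs(eval_basis(basis, tt) -
                      deboor_design(basis$knots, tt, basis$order))), 1e-10)
})

test_that("a constant record is fitted exactly at any lambda", {
  Y <- matrix(4.0, 5, 2)
  for (lam in c(1e-6, 1, 1e6)) {
    fit <- fit_ogtt_curves(Y, basis, lam)
    expect_lt(max(abs(predict(fit, seq(0, 120, 3)) - 4.0)), 1e-8)
  }
})

test_that("limits of the smoother: interpolation and straight lines", {
  coh <- simulate_ogtt_cohort(40, seed = 5, missing_fraction = 0)
  Y <- cohort_matrix(coh)
  # lambda -> 0: near interpolation of the five measurements
  fit0 <- fit_ogtt_curves(Y, basis, 1e-8)
  expect_lt(max(abs(fitted(fit0) - Y)), 1e-3)
  # lambda -> Inf: per-subject least-squares straight line (penalty null
  # space is linear)
  fitI <- fit_ogtt_curves(Y, basis, 1e8)
  tms <- ogtt_times()
  for (i in seq_len(ncol(Y))) {
    line <- lm(Y[, i] ~ tms)
    expect_lt(max(abs(predict(fitI, tms)[, i] - fitted(line))), 1e-3)
  }
  # singular unpenalized system is refused with advice
  expect_error(fit_ogtt_curves(Y, basis, 0), "positive 'lambda'")
})

test_that("smoother is linear in the data", {
  set.seed(8)
  Y1 <- matrix(rnorm(10, 5), 5, 2)
  Y2 <- matrix(rnorm(10, 5), 5, 2)
  f <- function(Y) fit_ogtt_curves(Y, basis, 12.3)$coefficients
  expect_lt(max(abs(f(2 * Y1 - 0.5 * Y2) - (2 * f(Y1) - 0.5 * f(Y2)))),
            1e-10)
})

test_that("roughness and dof shrink as lambda grows; SSE grows", {
  coh <- simulate_ogtt_cohort(25, seed = 6, missing_fraction = 0)
  Y <- cohort_matrix(coh)
  lams <- 10^seq(-3, 5)
  fits <- lapply(lams, function(l) fit_ogtt_curves(Y, basis, l))
  dofs <- vapply(fits, function(f) f$dof, numeric(1L))
  rough <- vapply(fits, function(f) sum(curve_roughness(f)), numeric(1L))
  sse <- vapply(fits, function(f) sum(f$sse), numeric(1L))
  expect_true(all(diff(dofs) < 0))
  expect_true(all(diff(rough) < 1e-10))
  expect_true(all(diff(sse) > -1e-10))
})

test_that("penalty quadratic form equals dense-grid quadrature of (x'')^2", {
  set.seed(13)
  for (rep in 1:5) {
    cc <- rnorm(basis$K)
    grid <- seq(0, 120, by = 0.02)
    d2 <- drop(eval_basis(basis, grid, deriv = 2L) %*% cc)
    quad <- sum(trap_weights(grid) * d2^2)
    expect_equal(drop(t(cc) %*% basis$R %*% cc), quad, tolerance = 1e-6)
  }
})

test_that("pooled GCV finds an interior minimum that beats the grid ends", {
  coh <- simulate_ogtt_cohort(200, seed = 21, missing_fraction = 0)
  Y <- cohort_matrix(coh)
  sel <- select_lambda_gcv(Y, basis)
  expect_gt(sel$lambda, 1e-4)
  expect_lt(sel$lambda, 1e4)
  # the selected lambda has smaller mean integrated squared error to the
  # generator's true curves than either grid endpoint
  grid <- seq(0, 120)
  truth <- ogtt_truth(coh, grid = grid)$true_curves
  mise <- function(lam)
    mean((predict(fit_ogtt_curves(Y, basis, lam), grid) - truth)^2)
  expect_lt(mise(sel$lambda), mise(min(sel$grid)))
  expect_lt(mise(sel$lambda), mise(max(sel$grid)))
  # deterministic for fixed input
  expect_identical(sel$lambda, select_lambda_gcv(Y, basis)$lambda)
})

test_that("per-curve GCV mode returns one lambda per subject", {
  coh <- simulate_ogtt_cohort(8, seed = 31, missing_fraction = 0)
  Y <- cohort_matrix(coh)
  sel <- select_lambda_gcv(Y, basis, mode = "per_curve")
  expect_length(sel$lambda, ncol(Y))
  fit <- fit_ogtt_curves(Y, basis, sel$lambda)
  expect_equal(ncol(fit$coefficients), ncol(Y))
})

test_that("curve evaluation is linear and refuses out-of-domain times", {
  coh <- simulate_ogtt_cohort(10, seed = 41, missing_fraction = 0)
  fit <- fit_ogtt_curves(cohort_matrix(coh), basis, 5)
  ev <- predict(fit, seq(0, 120, 7.5))
  expect_equal(rowMeans(ev),
               drop(eval_basis(basis, seq(0, 120, 7.5)) %*%
                      rowMeans(fit$coefficients)), tolerance = 1e-12)
  expect_error(predict(fit, c(50, 121)), "within")
})
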