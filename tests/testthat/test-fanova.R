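basis <- ogtt_basis()

# two-group synthetic functional sample: group 2 shifted by `shift` mmol/l
two_group_fit <- function(n_per, shift = 0, noise = 0.15, seed = 1) {
  set.seed(seed)
  tms <- ogtt_times()
  mu <- mean_glucose_curve()(tms)
  n <- 2L * n_per
  lvl <- rnorm(n, 0, 0.5)
  Y <- matrix(mu, 5, n) + rep(lvl, each = 5) +
    matrix(rnorm(5 * n, 0, noise), 5, n)
  Y[, seq_len(n_per) + n_per] <- Y[, seq_len(n_per) + n_per] + shift
  list(fit = fit_ogtt_curves(Y, basis, 10),
       labels = rep(c("g1", "g2"), each = n_per))
}

test_that("estimates: reference coding, exact shifts, OLS oracle", {
  tg <- two_group_fit(30, shift = 0, seed = 2)
  # make group 2 exactly group 1 + 0.5
  fit <- tg$fit
  fit$coefficients[, 31:60] <- fit$coefficients[, 1:30]
  fit$coefficients[1:7, 31:60] <- fit$coefficients[1:7, 1:30] +
    0.5 * qr.solve(eval_basis(basis, seq(0, 120, 20)),
                   rep(1, 7))   # coefficients of the constant 1
  fv <- ogtt_fanova(fit, tg$labels, reference = "g1", B = 0)
  expect_lt(max(abs(fv$beta[, "g2"] - 0.5)), 1e-10)

  # general case: estimates equal per-grid-point OLS with reference coding
  tg <- two_group_fit(25, shift = 0.3, seed = 3)
  grid <- seq(0, 120, 5)
  fv <- ogtt_fanova(tg$fit, tg$labels, reference = "g1", grid = grid, B = 0)
  X <- predict(tg$fit, grid)
  for (j in c(1L, 13L, 25L)) {
    ols <- lm(X[j, ] ~ factor(tg$labels))
    expect_equal(unname(fv$beta_ref[j]), unname(coef(ols)[1L]),
                 tolerance = 1e-10)
    expect_equal(unname(fv$beta[j, "g2"]), unname(coef(ols)[2L]),
                 tolerance = 1e-10)
  }

  # single category: reference curve is the overall mean, no contrasts
  one <- ogtt_fanova(tg$fit, rep("all", 50), B = 0)
  expect_equal(one$beta_ref, rowMeans(predict(tg$fit, one$grid)),
               tolerance = 1e-10)
  expect_equal(ncol(one$beta), 0L)
})

test_that("group decomposition identity and F invariance", {
  coh <- simulate_ogtt_cohort(120, seed = 4, missing_fraction = 0)
  fit <- fit_ogtt_curves(cohort_matrix(coh), basis, 20)
  g <- factor(coh$bmi_category)
  keep <- !is.na(g)
  fv <- ogtt_fanova(fit, g, reference = "normal", B = 0)
  X <- predict(fit, fv$grid)[, keep]
  gm <- sapply(levels(droplevels(g[keep])), function(lv)
    rowMeans(X[, g[keep] == lv, drop = FALSE]))
  sizes <- table(droplevels(g[keep]))
  expect_equal(gm %*% as.numeric(sizes), rowSums(X), tolerance = 1e-10,
               ignore_attr = TRUE)

  # F(t) invariant to adding a fixed function of t to all curves
  fv1 <- ogtt_fanova(fit, g, reference = "normal", B = 0)
  fit2 <- fit
  fit2$coefficients <- fit$coefficients + rnorm(basis$K)
  fv2 <- ogtt_fanova(fit2, g, reference = "normal", B = 0)
  expect_equal(fv1$F_curve, fv2$F_curve, tolerance = 1e-8)
})

test_that("permutation test: determinism, bounds, and power", {
  tg <- two_group_fit(100, shift = 1.0, noise = 0.15, seed = 5)
  fv1 <- ogtt_fanova(tg$fit, tg$labels, B = 199, seed = 11)
  fv2 <- ogtt_fanova(tg$fit, tg$labels, B = 199, seed = 11)
  expect_identical(fv1$p_curve, fv2$p_curve)
  expect_identical(fv1$p_overall, fv2$p_overall)
  # effect >> noise: no permuted max-F reaches the observed one
  expect_equal(fv1$p_overall, 1 / 200)
  expect_true(all(fv1$p_curve >= 1 / 200 & fv1$p_curve <= 1))
  expect_true(all(fv1$F_curve >= 0))
  expect_error(ogtt_fanova(tg$fit, tg$labels, B = -1), "B")
})

test_that("pointwise confidence bands contain the estimate and scale", {
  tg <- two_group_fit(25, shift = 0.4, seed = 6)
  fv <- ogtt_fanova(tg$fit, tg$labels, B = 0)
  expect_true(all(fv$ci_lower <= fv$beta & fv$beta <= fv$ci_upper))
  # quadrupling n about halves the band width
  tg4 <- two_group_fit(100, shift = 0.4, seed = 6)
  fv4 <- ogtt_fanova(tg4$fit, tg4$labels, B = 0)
  ratio <- mean((fv4$ci_upper - fv4$ci_lower) /
                  (fv$ci_upper - fv$ci_lower))
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
})

test_that("pairwise comparisons return one overall p per category pair", {
  coh <- simulate_ogtt_cohort(200, seed = 7, missing_fraction = 0)
  fit <- fit_ogtt_curves(cohort_matrix(coh), basis, 20)
  g <- factor(coh$bmi_category)
  g[g == "underweight"] <- NA          # tiny group would break permutation
  pw <- fanova_pairwise(fit, droplevels(g), B = 99, seed = 8)
  expect_equal(nrow(pw), choose(nlevels(droplevels(g)), 2L))
  expect_true(all(pw$p_overall >= 1 / 100 & pw$p_overall <= 1))
})

test_that("missing labels are dropped and counted", {
  tg <- two_group_fit(20, shift = 0.2, seed = 9)
  lab <- tg$labels
  lab[c(3, 17)] <- NA
  fv <- ogtt_fanova(tg$fit, lab, B = 0)
  expect_equal(fv$n_dropped, 2L)
  expect_equal(sum(fv$group_n), 38L)
})
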