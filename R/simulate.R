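#' Orthonormal modes of variation used by the cohort generator
#'
#' Three functions on \[0, 120\], mutually orthonormal in L2:
#' a normalized constant (a level shift, the dominant feature of OGTT
#' samples), a centred linear ramp proportional to t - 60 (an
#' early-versus-late contrast, shifting the time to peak), and a
#' one-cycle cosine (an oscillation). The ramp and cosine integrate to
#' zero over the domain, so only the level mode moves the area under the
#' curve.
#'
#' @return A list of three vectorized functions of time in minutes.
#' @examples
#' m <- default_modes()
#' integrate(function(t) m[[1]](t)^2, 0, 120)$value  # 1
#' @export
default_modes <- function() {
  list(
    level = function(t) rep(1 / sqrt(120), length(t)),
    ramp = function(t) (t - 60) / sqrt(144000),
    cosine = function(t) cos(2 * pi * t / 120) / sqrt(60)
  )
}

#' Population mean glucose curve of the generator
#'
#' Natural cubic interpolant through the anchor values at the canonical
#' times (defaults 4.0, 5.7, 5.0, 4.5, 4.1 mmol/l — the time-point means
#' of a healthy early-pregnancy population).
#'
#' @param mean_values Glucose anchors at 0, 30, 60, 90, 120 min.
#' @return A vectorized function of time in minutes.
#' @export
mean_glucose_curve <- function(mean_values = c(4.0, 5.7, 5.0, 4.5, 4.1)) {
  splinefun(ogtt_times(), mean_values, method = "natural")
}

#' Simulate a synthetic OGTT cohort with known ground truth
#'
#' Generates subject-level five-point OGTTs with the statistical
#' structure the analysis pipeline assumes: subject i's true curve is
#' \deqn{x_i(t) = \mu(t) + \sum_k z_{ki} \xi_k(t) + s_{b(i)}}
#' with a smooth population mean \eqn{\mu}, three orthonormal modes
#' \eqn{\xi_k} ([default_modes()]) with independent Gaussian scores
#' \eqn{z_{ki} \sim N(0, \sigma_k^2)}, and an additive level shift
#' \eqn{s_b} per BMI category. Observations are the true curve at the
#' canonical times plus independent Gaussian measurement noise. A later
#' 2-h outcome is linear in the first two scores plus noise. A fixed
#' fraction of subjects (`round(missing_fraction * n)`, deterministic
#' count) lose one randomly chosen time point.
#'
#' The default score SDs (6.0, 1.87, 0.99) put the three modes' variance
#' shares at roughly 88/9/2 percent of the total, matching the
#' concentration typical of OGTT curve samples; the constant-mode SD of
#' 6.0 corresponds to a subject-level level-shift SD of
#' 6.0/sqrt(120) = 0.55 mmol/l.
#'
#' @param n_subjects Number of subjects.
#' @param mean_values Mean-curve anchors at the canonical times (mmol/l).
#' @param score_sds SDs of the three mode scores.
#' @param noise_sd Measurement noise SD in mmol/l.
#' @param bmi_probs Probabilities of the four BMI categories
#'   (underweight, normal, overweight, obese). May sum to slightly less
#'   than 1; the remainder is the probability of a missing BMI.
#' @param bmi_shifts Additive glucose shift (mmol/l) per BMI category.
#' @param outcome_coef `c(a0, a1, a2)`: the later 2-h outcome is
#'   `a0 + a1 * z1 + a2 * z2 + noise`.
#' @param outcome_sd SD of the outcome noise (mmol/l).
#' @param missing_fraction Fraction of subjects with one deleted time
#'   point.
#' @param seed Optional integer seed; fixed seed gives bit-identical
#'   cohorts.
#' @return An [ogtt_cohort()] with covariates `bmi`, `bmi_category`,
#'   `outcome_2h_late`, and a `"truth"` attribute (see [ogtt_truth()]).
#' @export
simulate_ogtt_cohort <- function(n_subjects,
                                 mean_values = c(4.0, 5.7, 5.0, 4.5, 4.1),
                                 score_sds = c(6.0, 1.87, 0.99),
                                 noise_sd = 0.15,
                                 bmi_probs = c(0.017, 0.604, 0.281, 0.089),
                                 bmi_shifts = c(0, 0, 0.25, 0.55),
                                 outcome_coef = c(5.5, 0.05, 0.10),
                                 outcome_sd = 1.0,
                                 missing_fraction = 0.055,
                                 seed = NULL) {
  n <- as.integer(n_subjects)
  if (n < 1L) stop("'n_subjects' must be positive")
  if (length(score_sds) != 3L || any(score_sds < 0))
    stop("'score_sds' must be three non-negative values")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (length(bmi_probs) != 4L || any(bmi_probs < 0) || sum(bmi_probs) > 1 + 1e-8)
    stop("'bmi_probs' must be four non-negative values summing to <= 1")
  if (missing_fraction < 0 || missing_fraction > 1)
    stop("'missing_fraction' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  tms <- ogtt_times()
  mu <- mean_glucose_curve(mean_values)
  modes <- default_modes()
  Xi <- vapply(modes, function(f) f(tms), numeric(length(tms)))  # J x 3

  z <- vapply(1:3, function(k) rnorm(n, 0, score_sds[k]), numeric(n))
  z <- matrix(z, nrow = n)

  cats <- c("underweight", "normal", "overweight", "obese")
  p_miss <- max(0, 1 - sum(bmi_probs))
  bmi_cat <- sample(c(cats, NA), n, replace = TRUE,
                    prob = c(bmi_probs, p_miss))
  bmi_ranges <- rbind(c(16.5, 18.5), c(18.5, 25), c(25, 30), c(30, 40))
  bmi <- rep(NA_real_, n)
  for (k in seq_along(cats)) {
    idx <- which(bmi_cat == cats[k])
    bmi[idx] <- runif(length(idx), bmi_ranges[k, 1L], bmi_ranges[k, 2L])
  }
  shift <- ifelse(is.na(bmi_cat), 0,
                  bmi_shifts[match(bmi_cat, cats)])

  true_at_times <- matrix(mu(tms), n, length(tms), byrow = TRUE) +
    z %*% t(Xi) + shift
  obs <- true_at_times + matrix(rnorm(n * length(tms), 0, noise_sd),
                                n, length(tms))

  outcome <- outcome_coef[1L] + outcome_coef[2L] * z[, 1L] +
    outcome_coef[3L] * z[, 2L] + rnorm(n, 0, outcome_sd)

  n_miss <- round(missing_fraction * n)
  if (n_miss > 0L) {
    who <- sample.int(n, n_miss)
    which_t <- sample.int(length(tms), n_miss, replace = TRUE)
    obs[cbind(who, which_t)] <- NA_real_
  }

  df <- data.frame(subject_id = sprintf("S%04d", seq_len(n)))
  for (j in seq_along(tms)) df[[paste0("g", tms[j])]] <- obs[, j]
  df$bmi <- bmi
  df$bmi_category <- bmi_cat
  df$outcome_2h_late <- outcome

  config <- list(n_subjects = n, mean_values = mean_values,
                 score_sds = score_sds, noise_sd = noise_sd,
                 bmi_probs = bmi_probs, bmi_shifts = bmi_shifts,
                 outcome_coef = outcome_coef, outcome_sd = outcome_sd,
                 missing_fraction = missing_fraction, seed = seed)
  coh <- ogtt_cohort(df, metadata = list(source = "simulate_ogtt_cohort",
                                         seed = seed, config = config))
  attr(coh, "truth") <- list(scores = z, bmi_shift = shift,
                             true_values = true_at_times, config = config)
  coh
}

#' Ground truth of a simulated cohort
#'
#' Exposes the generator's per-subject true scores and true curves, for
#' parameter-recovery tests only; the analysis stages never consume it.
#'
#' @param cohort A cohort produced by [simulate_ogtt_cohort()].
#' @param grid Optional times at which to evaluate the true curves.
#' @return A list: `scores` (n x 3 true mode scores), `bmi_shift`,
#'   `config`, and — when `grid` is given — `true_curves`
#'   (`length(grid)` x n matrix).
#' @export
ogtt_truth <- function(cohort, grid = NULL) {
  tr <- attr(cohort, "truth")
  if (is.null(tr))
    stop("cohort carries no truth bundle; was it produced by ",
         "simulate_ogtt_cohort()?")
  if (!is.null(grid)) {
    cfg <- tr$config
    mu <- mean_glucose_curve(cfg$mean_values)
    Xi <- vapply(default_modes(), function(f) f(grid),
                 numeric(length(grid)))
    tr$true_curves <- matrix(mu(grid), length(grid), nrow(tr$scores)) +
      Xi %*% t(tr$scores) +
      matrix(tr$bmi_shift, length(grid), nrow(tr$scores), byrow = TRUE)
  }
  tr
}
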