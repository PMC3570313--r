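#' Run the full OGTT functional-data-analysis pipeline
#'
#' Orchestrates the end-to-end analysis: completeness filtering, penalized
#' B-spline smoothing with a pooled-GCV smoothing parameter, functional
#' PCA, simple summary measures and their correlation with the FPC scores,
#' one-way ANOVA of the summaries across BMI categories, functional ANOVA
#' across BMI categories with pairwise permutation tests, and multinomial
#' regression of the categorized later 2-h outcome on curve features
#' (five models: FPC scores, fasting value, 2-h value, AUC, shape index —
#' each together with BMI).
#'
#' Stages that need covariates absent from the cohort (BMI, later
#' outcome) are skipped silently. All randomness flows from `seed`:
#' the generator uses `seed`, the functional ANOVA permutations
#' `seed + 1`. Re-running with identical inputs reproduces identical
#' outputs.
#'
#' @param cohort An [ogtt_cohort()]; if `NULL`, a synthetic cohort of
#'   `n_subjects` is generated with [simulate_ogtt_cohort()].
#' @param n_subjects Size of the generated cohort when `cohort` is NULL.
#' @param seed Integer master seed.
#' @param lambda Smoothing parameter; `NULL` selects it by pooled GCV.
#' @param n_components Retained FPC count; default 3.
#' @param B Permutations for the functional ANOVA.
#' @param shape_threshold Shape-classification threshold (mmol/l).
#' @param grid Evaluation grid in minutes.
#' @return Object of class `ogtt_pipeline`: a list with `cohort`
#'   (retained records), `filter` (exclusion report), `fit`, `lambda`,
#'   `fpca`, `summaries`, `correlations`, `anova` (per summary measure,
#'   across BMI categories), `fanova`, `fanova_pairwise`, `regression`
#'   (per model), and `manifest` (counts, seeds, lambda, B).
#' @export
run_ogtt_pipeline <- function(cohort = NULL, n_subjects = 974L, seed = 1L,
                              lambda = NULL, n_components = 3L, B = 1000L,
                              shape_threshold = 0.25, grid = seq(0, 120)) {
  if (is.null(cohort))
    cohort <- simulate_ogtt_cohort(n_subjects, seed = seed)
  stopifnot(inherits(cohort, "ogtt_cohort"))

  flt <- filter_complete(cohort)
  coh <- flt$cohort
  Y <- cohort_matrix(coh)
  basis <- ogtt_basis()

  if (is.null(lambda)) {
    sel <- select_lambda_gcv(Y, basis)
    lambda <- sel$lambda
  }
  fit <- fit_ogtt_curves(Y, basis, lambda)
  pca <- ogtt_fpca(fit, n_components = n_components)
  scores <- pca$scores[, seq_len(n_components), drop = FALSE]
  colnames(scores) <- paste0("fpc", seq_len(n_components))

  summ <- ogtt_summaries(coh, threshold = shape_threshold)
  corr <- correlation_table(summ, scores)

  anova_res <- fanova_res <- pairwise_res <- NULL
  if ("bmi_category" %in% names(coh) && any(!is.na(coh$bmi_category))) {
    g <- factor(coh$bmi_category,
                levels = c("underweight", "normal", "overweight", "obese"))
    anova_res <- lapply(
      list(fasting = summ$fasting, two_hour = summ$v120, auc = summ$auc,
           shape_index = summ$shape_index),
      function(v) tryCatch(anova_summary_measures(v, g),
                           error = function(e) NULL))
    # permutation inference needs >= 2 subjects per category; singleton
    # categories are set aside for the functional ANOVA stage
    counts <- table(g)
    g_f <- g
    g_f[g_f %in% names(counts[counts < 2L])] <- NA
    g_f <- droplevels(g_f)
    if (nlevels(g_f) >= 2L && "normal" %in% levels(g_f)) {
      fanova_res <- ogtt_fanova(fit, g_f, reference = "normal", grid = grid,
                                B = B, seed = seed + 1L)
      pairwise_res <- fanova_pairwise(fit, g_f, grid = grid, B = B,
                                      seed = seed + 1L)
    }
  }

  regression <- NULL
  if ("outcome_2h_late" %in% names(coh) && "bmi" %in% names(coh)) {
    outc <- categorize_outcome(coh$outcome_2h_late)
    covs <- list(
      fpc_scores = cbind(data.frame(bmi = coh$bmi), as.data.frame(scores)),
      fasting = data.frame(bmi = coh$bmi, fasting = summ$fasting),
      two_hour = data.frame(bmi = coh$bmi, two_hour = summ$v120),
      auc = data.frame(bmi = coh$bmi, auc = summ$auc),
      shape_index = data.frame(bmi = coh$bmi,
                               shape_index = summ$shape_index))
    regression <- lapply(names(covs), function(id)
      tryCatch(ogtt_multinom(outc, covs[[id]], model_id = id),
               error = function(e) NULL))
    names(regression) <- names(covs)
  }

  manifest <- list(
    n_input = flt$report$n_input, n_retained = flt$report$n_retained,
    n_excluded = flt$report$n_excluded,
    pct_excluded = flt$report$pct_excluded,
    lambda = lambda, dof = fit$dof, seed = seed, B = B,
    n_components = n_components,
    variance_proportions = pca$variance_proportions[seq_len(n_components)],
    shape_counts = table(summ$shape_label))

  structure(list(cohort = coh, filter = flt, fit = fit, lambda = lambda,
                 fpca = pca, scores = scores, summaries = summ,
                 correlations = corr, anova = anova_res,
                 fanova = fanova_res, fanova_pairwise = pairwise_res,
                 regression = regression, grid = grid,
                 manifest = manifest),
            class = "ogtt_pipeline")
}

#' @export
print.ogtt_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("OGTT FDA pipeline\n")
  cat(sprintf("  subjects: %d in, %d retained, %d excluded (%.1f%%)\n",
              m$n_input, m$n_retained, m$n_excluded, m$pct_excluded))
  cat(sprintf("  lambda = %.4g (df = %.2f)\n", m$lambda, m$dof))
  cat(sprintf("  FPC variance: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * m$variance_proportions),
                    collapse = ", "),
              100 * sum(m$variance_proportions)))
  if (!is.null(x$fanova))
    cat(sprintf("  FANOVA overall permutation p = %.4g\n",
                x$fanova$p_overall))
  invisible(x)
}

#' Export plot-ready data files from a pipeline run
#'
#' Writes CSVs sufficient to redraw the standard displays: the fitted
#' curves on the evaluation grid with the sample mean; mode-of-variation
#' curves per retained component; FPC1/FPC2 quartile-panel assignments;
#' functional-ANOVA contrast curves with confidence bands; F and
#' point-wise p curves; mean fitted curves per outcome category; plus a
#' JSON manifest (counts, lambda, seed, B).
#'
#' @param pipeline A [run_ogtt_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
export_figure_data <- function(pipeline, out_dir) {
  stopifnot(inherits(pipeline, "ogtt_pipeline"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }

  grid <- pipeline$grid
  curves <- predict(pipeline$fit, grid)
  colnames(curves) <- pipeline$cohort$subject_id
  put(data.frame(t = grid, mean = rowMeans(curves), curves,
                 check.names = FALSE), "fitted_curves.csv")

  m <- pipeline$fpca$n_components
  modes <- do.call(rbind, lapply(seq_len(m), function(k)
    cbind(component = k, mode_curves(pipeline$fpca, k, t = grid))))
  put(modes, "mode_curves.csv")

  qp <- quartile_panels(pipeline$scores)
  put(cbind(subject_id = pipeline$cohort$subject_id, qp,
            as.data.frame(pipeline$scores)), "score_panels.csv")
  put(cbind(subject_id = pipeline$cohort$subject_id,
            as.data.frame(pipeline$scores)), "fpc_scores.csv")
  put(as.data.frame(summary(pipeline$fpca)), "variance_table.csv")
  put(pipeline$summaries, "summary_measures.csv")
  put(data.frame(variable = rownames(pipeline$correlations),
                 pipeline$correlations, check.names = FALSE),
      "correlation_table.csv")

  if (!is.null(pipeline$fanova)) {
    fv <- pipeline$fanova
    bands <- do.call(rbind, lapply(colnames(fv$beta), function(cat)
      data.frame(category = cat, t = fv$grid, beta = fv$beta[, cat],
                 ci_lower = fv$ci_lower[, cat],
                 ci_upper = fv$ci_upper[, cat])))
    put(bands, "fanova_bands.csv")
    put(data.frame(t = fv$grid, F = fv$F_curve, p = fv$p_curve),
        "fanova_curves.csv")
    put(pipeline$fanova_pairwise, "fanova_pairwise.csv")
  }

  if (!is.null(pipeline$regression) &&
      "outcome_2h_late" %in% names(pipeline$cohort)) {
    outc <- categorize_outcome(pipeline$cohort$outcome_2h_late)
    keep <- !is.na(outc)
    cm <- vapply(levels(outc), function(lv) {
      idx <- which(keep & outc == lv)
      if (length(idx)) rowMeans(curves[, idx, drop = FALSE])
      else rep(NA_real_, length(grid))
    }, numeric(length(grid)))
    put(data.frame(t = grid, cm, check.names = FALSE),
        "outcome_category_mean_curves.csv")
    for (id in names(pipeline$regression)) {
      mf <- pipeline$regression[[id]]
      if (!is.null(mf)) put(mf$table, paste0("regression_", id, ".csv"))
    }
  }

  mf <- pipeline$manifest
  mf$shape_counts <- as.list(mf$shape_counts)
  jp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(mf, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, jp)
  invisible(paths)
}
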