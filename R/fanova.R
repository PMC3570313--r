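#' Functional analysis of variance of OGTT curves
#'
#' Compares the mean curves of mutually exclusive categories. The model
#' is \eqn{x_{lg}(t) = \beta_{ref}(t) + \beta_g(t) + \epsilon_{lg}(t)}
#' with reference coding: \eqn{\beta_{ref}(t)} is the mean fitted curve
#' of the reference category and \eqn{\beta_g(t)} the difference between
#' the category-g mean curve and the reference. Inference combines:
#'
#' * the point-wise F statistic
#'   \eqn{F(t) = [SSB(t)/(G-1)] / [SSW(t)/(n-G)]} (between-group mean
#'   square over within-group mean square);
#' * a permutation distribution obtained by shuffling whole-curve labels
#'   `B` times, giving a point-wise p-value curve
#'   \eqn{p(t) = (1 + \#\{F_b(t) \ge F(t)\})/(B+1)} and an overall
#'   p-value from the permutation distribution of \eqn{\max_t F_b(t)};
#' * point-wise normal-theory confidence bands
#'   \eqn{\beta_g(t) \pm z_{1-\alpha/2} SE(t)} with the standard error
#'   from the pooled within-group variance at each t.
#'
#' Subjects with missing labels are dropped (their count is recorded in
#' the result).
#'
#' @param fit An [fit_ogtt_curves()] result.
#' @param labels Category label per subject (factor or coercible);
#'   `NA` allowed.
#' @param reference Reference category; default the first factor level.
#' @param grid Evaluation times in minutes; default 1-minute steps.
#' @param B Number of permutations (default 1000); `B = 0` skips the
#'   permutation test.
#' @param ci_level Confidence level for the point-wise bands.
#' @param seed Optional integer seed for the permutations.
#' @return Object of class `ogtt_fanova`: `grid`, `beta_ref`, `beta`
#'   (grid x categories matrix of contrasts), `ci_lower`/`ci_upper`,
#'   `F_curve`, `p_curve`, `p_overall`, `B`, `seed`, `categories`,
#'   `reference`, `group_n`, `n_dropped`.
#' @export
ogtt_fanova <- function(fit, labels, reference = NULL, grid = seq(0, 120),
                        B = 1000L, ci_level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "ogtt_curvefit"))
  labels <- factor(labels)
  if (length(labels) != fit$n)
    stop("'labels' must have one entry per fitted curve")
  if (B < 0L) stop("'B' must be >= 0")
  keep <- !is.na(labels)
  n_dropped <- sum(!keep)
  g <- droplevels(labels[keep])
  if (is.null(reference)) reference <- levels(g)[1L]
  if (!reference %in% levels(g)) stop("reference category '", reference,
                                      "' not present among labels")
  g <- stats::relevel(g, ref = reference)
  G <- nlevels(g)
  n <- length(g)
  if (any(tabulate(g) < 1L)) stop("every category needs >= 1 subject")

  X <- eval_basis(fit$basis, grid) %*% fit$coefficients[, keep, drop = FALSE]
  Tn <- length(grid)
  sizes <- tabulate(g)
  ind <- outer(as.integer(g), seq_len(G), "==") + 0   # n x G

  group_means <- (X %*% ind) %*% diag(1 / sizes, G)
  colnames(group_means) <- levels(g)
  overall <- rowMeans(X)
  beta_ref <- group_means[, 1L]
  beta <- group_means[, -1L, drop = FALSE] - beta_ref

  TSS <- rowSums((X - overall)^2)
  BSS <- rowSums(t(t(group_means^2) * sizes)) - n * overall^2
  WSS <- pmax(TSS - BSS, 0)

  F_curve <- p_curve <- p_overall <- NULL
  if (G >= 2L && n > G) {
    F_curve <- (BSS / (G - 1)) / (WSS / (n - G))
    if (B >= 1L) {
      if (any(sizes < 2L))
        stop("permutation test needs >= 2 subjects per category")
      if (!is.null(seed)) set.seed(seed)
      Fmax <- numeric(B)
      exceed <- numeric(Tn)
      gi <- as.integer(g)
      for (b in seq_len(B)) {
        gp <- gi[sample.int(n)]
        indp <- outer(gp, seq_len(G), "==") + 0
        gm <- (X %*% indp) %*% diag(1 / sizes, G)
        BSSb <- rowSums(t(t(gm^2) * sizes)) - n * overall^2
        Fb <- (BSSb / (G - 1)) / (pmax(TSS - BSSb, 0) / (n - G))
        exceed <- exceed + (Fb >= F_curve)
        Fmax[b] <- max(Fb)
      }
      p_curve <- (1 + exceed) / (B + 1)
      p_overall <- (1 + sum(Fmax >= max(F_curve))) / (B + 1)
    }
  }

  # point-wise bands for the contrasts, pooled within-group variance
  s2 <- WSS / (n - G)
  zq <- qnorm(1 - (1 - ci_level) / 2)
  se <- sqrt(outer(s2, 1 / sizes[-1L] + 1 / sizes[1L]))
  ci_lower <- beta - zq * se
  ci_upper <- beta + zq * se

  structure(list(grid = grid, beta_ref = beta_ref, beta = beta,
                 ci_lower = ci_lower, ci_upper = ci_upper,
                 F_curve = F_curve, p_curve = p_curve,
                 p_overall = p_overall, B = as.integer(B), seed = seed,
                 categories = levels(g), reference = reference,
                 group_n = setNames(sizes, levels(g)),
                 ci_level = ci_level, n_dropped = n_dropped),
            class = "ogtt_fanova")
}

#' Pairwise functional permutation comparisons
#'
#' Re-runs the two-category functional ANOVA for every pair of
#' categories (refitting on the two categories' subjects only) and
#' collects the overall permutation p-values.
#'
#' @inheritParams ogtt_fanova
#' @return Data frame: `category_a`, `category_b`, `p_overall`.
#' @export
fanova_pairwise <- function(fit, labels, grid = seq(0, 120), B = 1000L,
                            seed = NULL) {
  labels <- factor(labels)
  lev <- levels(droplevels(labels[!is.na(labels)]))
  pairs <- utils::combn(lev, 2L)
  if (!is.null(seed)) set.seed(seed)
  out <- apply(pairs, 2L, function(pr) {
    sel <- !is.na(labels) & labels %in% pr
    sub <- subset_curvefit(fit, sel)
    fv <- ogtt_fanova(sub, droplevels(labels[sel]), reference = pr[1L],
                      grid = grid, B = B, seed = NULL)
    fv$p_overall
  })
  data.frame(category_a = pairs[1L, ], category_b = pairs[2L, ],
             p_overall = out)
}

# restrict a curve fit to a subset of subjects
subset_curvefit <- function(fit, idx) {
  out <- fit
  out$coefficients <- fit$coefficients[, idx, drop = FALSE]
  out$fitted <- fit$fitted[, idx, drop = FALSE]
  out$Y <- fit$Y[, idx, drop = FALSE]
  out$sse <- fit$sse[idx]
  if (length(fit$lambda) > 1L) out$lambda <- fit$lambda[idx]
  if (length(fit$dof) > 1L) out$dof <- fit$dof[idx]
  out$n <- ncol(out$coefficients)
  out
}

#' @export
print.ogtt_fanova <- function(x, ...) {
  cat("Functional ANOVA:", length(x$categories), "categories, reference =",
      x$reference, "\n")
  cat("group sizes:", paste(names(x$group_n), x$group_n, sep = "=",
                            collapse = ", "), "\n")
  if (x$n_dropped) cat(x$n_dropped, "subject(s) dropped (missing label)\n")
  if (!is.null(x$p_overall))
    cat(sprintf("overall permutation p = %.4g (B = %d, max-F statistic)\n",
                x$p_overall, x$B))
  invisible(x)
}
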