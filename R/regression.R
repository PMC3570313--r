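#' Categorize the later-pregnancy 2-h glucose outcome
#'
#' Groups 2-h glucose values into seven ordered categories with
#' left-closed, right-open intervals. The default cutpoints follow the
#' clinical percentile scheme anchored at the WHO gestational-diabetes
#' threshold of 7.8 mmol/l, with \[3.89, 6.39) as the reference
#' category. A boundary value falls in the upper interval (half-open
#' convention), so 7.8 itself is in \[7.8, 8.84).
#'
#' @param values 2-h glucose in mmol/l; `NA` yields `NA` labels.
#' @param cutpoints Ordered interior cutpoints; default
#'   `c(3.27, 3.89, 6.39, 6.90, 7.8, 8.84)`.
#' @param reference Index of the reference interval among the
#'   `length(cutpoints) + 1` categories; default 3.
#' @return A factor with the reference category as first level and an
#'   attribute `"reference"` naming it.
#' @export
categorize_outcome <- function(values,
                               cutpoints = c(3.27, 3.89, 6.39, 6.90,
                                             7.8, 8.84),
                               reference = 3L) {
  if (is.unsorted(cutpoints, strictly = TRUE))
    stop("'cutpoints' must be strictly increasing")
  k <- length(cutpoints)
  labs <- c(paste0("<", cutpoints[1L]),
            if (k > 1L) sprintf("[%s,%s)", cutpoints[-k], cutpoints[-1L]),
            paste0(">=", cutpoints[k]))
  f <- cut(values, breaks = c(-Inf, cutpoints, Inf), labels = labs,
           right = FALSE)
  f <- stats::relevel(f, ref = labs[reference])
  attr(f, "reference") <- labs[reference]
  f
}

#' Multinomial logistic regression of the categorized outcome
#'
#' Fits a multinomial logit of the outcome category on the supplied
#' continuous covariates (maximum likelihood via [nnet::multinom()]),
#' and reports per-category odds ratios with Wald 95% confidence
#' intervals and p-values, covariate means/SDs per category, and Wald
#' comparisons of adjacent non-reference categories.
#'
#' Complete-case analysis: subjects with a missing outcome or covariate
#' are dropped and counted. Empty outcome categories are dropped with a
#' warning. Coefficients larger than 20 on the per-SD scale are flagged
#' as possible separation.
#'
#' @param outcome Factor from [categorize_outcome()] (reference level
#'   first).
#' @param covariates Data frame of continuous covariates (e.g. `bmi`
#'   plus FPC scores or one simple summary measure).
#' @param model_id Optional label (e.g. `"fpc_scores"`, `"auc"`).
#' @return Object of class `ogtt_multinom`: `fit` (the `multinom`
#'   object), `coefficients`, `vcov`, `table` (long data frame with OR,
#'   CI, p per category x covariate), `category_stats` (covariate mean/SD
#'   and n per category), `between_category_p`, `n_used`, `n_dropped`,
#'   `log_lik`, `converged`, `separation`, `model_id`.
#' @export
ogtt_multinom <- function(outcome, covariates, model_id = "model") {
  covariates <- as.data.frame(covariates)
  stopifnot(is.factor(outcome), nrow(covariates) == length(outcome))
  cc <- !is.na(outcome) & !Reduce(`|`, lapply(covariates, is.na))
  n_dropped <- sum(!cc)
  y <- droplevels(outcome[cc])
  X <- covariates[cc, , drop = FALSE]
  if (nlevels(y) < nlevels(outcome))
    warning("empty outcome categor(ies) dropped: ",
            paste(setdiff(levels(outcome), levels(y)), collapse = ", "))
  dat <- cbind(.y = y, X)

  fit <- nnet::multinom(.y ~ ., data = dat, Hessian = TRUE, trace = FALSE,
                        maxit = 500L, reltol = 1e-12)
  co <- coef(fit)                       # (L-1) x (1 + p)
  if (is.null(dim(co)))                 # two-category fit returns a vector
    co <- matrix(co, nrow = 1L,
                 dimnames = list(levels(y)[2L], names(co)))
  V <- vcov(fit)
  se <- matrix(sqrt(diag(V)), nrow = nrow(co), byrow = TRUE,
               dimnames = dimnames(co))

  sds <- vapply(X, sd, numeric(1L))
  sep <- any(abs(t(t(co[, -1L, drop = FALSE]) * sds)) > 20)
  if (sep) warning("possible separation: a standardized coefficient ",
                   "exceeds 20; estimates may be unstable")

  zq <- qnorm(0.975)
  rows <- expand.grid(category = rownames(co),
                      covariate = colnames(co)[-1L],
                      stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    cat <- rows$category[i]; cv <- rows$covariate[i]
    b <- co[cat, cv]; s <- se[cat, cv]
    data.frame(category = cat, covariate = cv, coef = b, se = s,
               or = exp(b), or_lower = exp(b - zq * s),
               or_upper = exp(b + zq * s),
               p = 2 * pnorm(-abs(b / s)))
  }))

  stats_by <- do.call(rbind, lapply(levels(y), function(lv) {
    sub <- X[y == lv, , drop = FALSE]
    data.frame(category = lv, n = nrow(sub),
               covariate = names(sub),
               mean = vapply(sub, mean, numeric(1L)),
               sd = vapply(sub, sd, numeric(1L)), row.names = NULL)
  }))

  res <- structure(list(fit = fit, coefficients = co, vcov = V,
                        table = tab, category_stats = stats_by,
                        n_used = sum(cc), n_dropped = n_dropped,
                        log_lik = as.numeric(logLik(fit)),
                        converged = fit$convergence == 0,
                        separation = sep, model_id = model_id,
                        levels = levels(y)),
                   class = "ogtt_multinom")
  res$between_category_p <- adjacent_category_p(res)
  res
}

# Wald p for equality of a covariate's coefficients in adjacent
# non-reference categories (reference has coefficient 0)
adjacent_category_p <- function(object) {
  cats <- rownames(object$coefficients)
  covs <- colnames(object$coefficients)[-1L]
  out <- expand.grid(category_a = cats[-length(cats)],
                     category_b = cats[-1L],
                     covariate = covs, stringsAsFactors = FALSE)
  out <- out[match(out$category_a, cats) + 1L ==
               match(out$category_b, cats), , drop = FALSE]
  out$p <- mapply(function(a, b, cv)
    compare_categories(object, cv, a, b), out$category_a, out$category_b,
    out$covariate)
  rownames(out) <- NULL
  out
}

#' Wald comparison of a covariate's effect between two outcome categories
#'
#' Tests equality of the covariate's multinomial-logit coefficients for
#' two categories using the joint estimated covariance. When one of the
#' two is the reference category its coefficient is identically zero, so
#' the test reduces to the single-coefficient Wald test.
#'
#' @param object An [ogtt_multinom()] fit.
#' @param covariate Covariate name.
#' @param category_a,category_b Category labels (non-reference or the
#'   reference level).
#' @return Two-sided p-value; comparing a category with itself gives 1.
#' @export
compare_categories <- function(object, covariate, category_a, category_b) {
  stopifnot(inherits(object, "ogtt_multinom"))
  if (identical(category_a, category_b)) return(1)
  co <- object$coefficients
  ref <- object$levels[1L]
  for (cat in c(category_a, category_b))
    if (!cat %in% c(rownames(co), ref))
      stop("category '", cat, "' not in the fitted model")
  if (!covariate %in% colnames(co))
    stop("covariate '", covariate, "' not in the fitted model")

  vn <- rownames(object$vcov)
  name_of <- function(cat) {
    cand <- paste(cat, covariate, sep = ":")
    if (nrow(co) == 1L) cand <- c(cand, covariate)
    hit <- cand[cand %in% vn]
    if (!length(hit)) stop("cannot locate coefficient for ", cat)
    hit[1L]
  }
  w <- setNames(numeric(length(vn)), vn)
  b <- 0
  if (category_a != ref) {
    w[name_of(category_a)] <- 1; b <- b + co[category_a, covariate]
  }
  if (category_b != ref) {
    w[name_of(category_b)] <- w[name_of(category_b)] - 1
    b <- b - co[category_b, covariate]
  }
  v <- drop(t(w) %*% object$vcov %*% w)
  2 * pnorm(-abs(b / sqrt(v)))
}

#' Predicted category probabilities
#'
#' @param object An [ogtt_multinom()] fit.
#' @param newdata Optional covariate data frame.
#' @param ... Unused.
#' @return Matrix of per-subject category probabilities (rows sum to 1).
#' @export
predict.ogtt_multinom <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) predict(object$fit, type = "probs")
  else predict(object$fit, newdata = newdata, type = "probs")
}

#' @export
print.ogtt_multinom <- function(x, ...) {
  cat("Multinomial logistic regression [", x$model_id, "]: ",
      length(x$levels), " categories (reference ", x$levels[1L], "), n = ",
      x$n_used, sep = "")
  if (x$n_dropped) cat(" (", x$n_dropped, " dropped)", sep = "")
  cat("\nlog-likelihood:", format(x$log_lik), "\n")
  print(x$table[, c("category", "covariate", "or", "or_lower", "or_upper",
                    "p")], digits = 3)
  invisible(x)
}
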