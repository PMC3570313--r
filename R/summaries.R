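#' Trapezoid area under the glucose curve
#'
#' AUC of the five raw measurements over \[0, 120\] minutes by the
#' trapezoid rule — the standard clinical convention, independent of any
#' smoothing. Units mmol·min/l.
#'
#' @param values Length-5 numeric vector (glucose at 0, 30, 60, 90,
#'   120 min) or a 5-row matrix / 5-column data frame of such records.
#' @return AUC per record.
#' @export
ogtt_auc <- function(values) {
  tms <- ogtt_times()
  f <- function(v) {
    if (length(v) != 5L) stop("a record has exactly 5 values")
    if (anyNA(v))
      stop("incomplete record: missing value at ",
           paste(tms[is.na(v)], collapse = ", "), " min")
    sum(diff(tms) * (v[-1L] + v[-5L]) / 2)
  }
  if (is.matrix(values)) apply(values, 2L, f)
  else if (is.data.frame(values)) apply(as.matrix(values), 1L, f)
  else f(as.numeric(values))
}

#' Rule-based classification of OGTT curve shape
#'
#' Compresses the five-point series into a sequence of significant
#' directional moves and labels the curve by the sign pattern. A move
#' counts only when the excursion from the last accepted turning value is
#' at least `threshold` (default 0.25 mmol/l, the empirical threshold in
#' the curve-shape literature); while a direction persists, the turning
#' value tracks the running extreme. Patterns: rise–fall is monophasic,
#' rise–fall–rise biphasic, rise–fall–rise–fall triphasic; anything else
#' (no significant move, an initial fall, or more than four moves) is
#' unclassified.
#'
#' The shape index is the 2-h minus the 90-min value for monophasic and
#' biphasic curves, the 90-min minus the 60-min value for triphasic
#' curves, and undefined for unclassified curves.
#'
#' @param values Length-5 numeric vector at the canonical times.
#' @param threshold Significant-excursion threshold in mmol/l.
#' @return A list of class `ogtt_shape`: `label` (one of `"monophasic"`,
#'   `"biphasic"`, `"triphasic"`, `"unclassified"`), `shape_index`
#'   (mmol/l, `NA` when unclassified) and `moves` (signed move pattern,
#'   e.g. `c(1, -1)`).
#' @examples
#' classify_shape(c(4.0, 5.7, 5.0, 4.5, 4.1))  # monophasic, index -0.4
#' @export
classify_shape <- function(values, threshold = 0.25) {
  values <- as.numeric(values)
  if (length(values) != 5L) stop("a record has exactly 5 values")
  if (anyNA(values))
    stop("incomplete record: missing value at ",
         paste(ogtt_times()[is.na(values)], collapse = ", "), " min")

  moves <- integer(0)
  ref <- values[1L]; dir <- 0L
  for (v in values[-1L]) {
    if (dir == 0L) {
      if (v - ref >= threshold) { dir <- 1L; moves <- c(moves, 1L); ref <- v }
      else if (ref - v >= threshold) { dir <- -1L; moves <- c(moves, -1L); ref <- v }
    } else if (dir == 1L) {
      if (v > ref) ref <- v
      else if (ref - v >= threshold) { dir <- -1L; moves <- c(moves, -1L); ref <- v }
    } else {
      if (v < ref) ref <- v
      else if (v - ref >= threshold) { dir <- 1L; moves <- c(moves, 1L); ref <- v }
    }
  }

  pat <- paste(moves, collapse = ",")
  label <- switch(pat,
                  "1,-1" = "monophasic",
                  "1,-1,1" = "biphasic",
                  "1,-1,1,-1" = "triphasic",
                  "unclassified")
  idx <- switch(label,
                monophasic = ,
                biphasic = values[5L] - values[4L],
                triphasic = values[4L] - values[3L],
                NA_real_)
  structure(list(label = label, shape_index = idx, moves = moves),
            class = "ogtt_shape")
}

#' @export
print.ogtt_shape <- function(x, ...) {
  cat("curve shape:", x$label)
  if (!is.na(x$shape_index))
    cat(sprintf(" (shape index %.2f mmol/l)", x$shape_index))
  cat("\n")
  invisible(x)
}

#' Simple summary measures per subject
#'
#' Computes the traditional OGTT summaries for every complete record in
#' a cohort: the five raw values, trapezoid AUC, and shape classification
#' with shape index.
#'
#' @param cohort A complete [ogtt_cohort()] (apply [filter_complete()]
#'   first).
#' @param threshold Shape-classification threshold in mmol/l.
#' @return Data frame with columns `subject_id`, `fasting`, `v30`, `v60`,
#'   `v90`, `v120`, `auc`, `shape_label`, `shape_index`.
#' @export
ogtt_summaries <- function(cohort, threshold = 0.25) {
  G <- cohort_matrix(cohort)
  shapes <- apply(G, 2L, classify_shape, threshold = threshold)
  data.frame(subject_id = cohort$subject_id,
             fasting = G[1L, ], v30 = G[2L, ], v60 = G[3L, ],
             v90 = G[4L, ], v120 = G[5L, ],
             auc = ogtt_auc(G),
             shape_label = vapply(shapes, `[[`, character(1L), "label"),
             shape_index = vapply(shapes, `[[`, numeric(1L), "shape_index"),
             row.names = NULL)
}

#' Pearson correlation table of measurements, summaries and scores
#'
#' Correlates the raw measurements and simple summary measures with FPC
#' scores (and with each other), using pairwise-complete observations so
#' that unclassified curves drop out of shape-index correlations only.
#' Zero-variance columns yield `NA` with a warning.
#'
#' @param summaries Output of [ogtt_summaries()].
#' @param scores Score matrix with one row per subject of `summaries`
#'   (e.g. the first columns of an [ogtt_fpca()] `scores` element).
#' @return Symmetric correlation matrix over fasting/v30/v60/v90/v120,
#'   AUC, shape index and the score columns.
#' @export
correlation_table <- function(summaries, scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) != nrow(summaries))
    stop("'scores' and 'summaries' describe different numbers of subjects")
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("fpc", seq_len(ncol(scores)))
  X <- cbind(summaries[, c("fasting", "v30", "v60", "v90", "v120", "auc",
                           "shape_index")],
             scores)
  if (nrow(X) < 3L) stop("need at least 3 subjects")
  sds <- vapply(X, sd, numeric(1L), na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("zero-variance column(s): ",
            paste(names(X)[which(sds == 0)], collapse = ", "),
            "; correlations undefined")
  suppressWarnings(cor(X, use = "pairwise.complete.obs"))
}

#' One-way ANOVA of a summary measure across groups
#'
#' Overall F test plus all pairwise comparisons with Bonferroni-corrected
#' p-values (pooled-SD post hoc, capped at 1). Pairs involving a group
#' with fewer than 2 members are undefined.
#'
#' @param values Numeric measure per subject.
#' @param groups Factor (or coercible) of group labels, e.g. BMI
#'   categories; `NA` groups are dropped.
#' @return A list of class `ogtt_anova`: `F`, `p`, `df`, `pairwise`
#'   (matrix of Bonferroni p-values), `group_means`, `group_n`.
#' @export
anova_summary_measures <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  x <- values[keep]; g <- droplevels(factor(groups[keep]))
  if (nlevels(g) < 2L) stop("need at least 2 non-empty groups")
  fit <- lm(x ~ g)
  at <- suppressWarnings(anova(fit))   # degenerate (perfect) fits handled below
  Fv <- at$`F value`[1L]; pv <- at$`Pr(>F)`[1L]
  if (at$`Sum Sq`[1L] < 1e-12) { Fv <- 0; pv <- 1 }  # identical group means
  small <- names(which(table(g) < 2L))
  pw <- suppressWarnings(
    pairwise.t.test(x, g, p.adjust.method = "bonferroni",
                    pool.sd = TRUE)$p.value)
  if (length(small)) {
    pw[rownames(pw) %in% small, ] <- NA
    pw[, colnames(pw) %in% small] <- NA
  }
  structure(list(F = Fv, p = pv,
                 df = at$Df, pairwise = pw,
                 group_means = tapply(x, g, mean),
                 group_n = table(g)),
            class = "ogtt_anova")
}

#' @export
print.ogtt_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$F, x$p))
  cat("Bonferroni pairwise p-values:\n")
  print(round(x$pairwise, 4))
  invisible(x)
}
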