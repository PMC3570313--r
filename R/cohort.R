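#' OGTT cohort objects
#'
#' A cohort is a wide data frame with one row per subject: a `subject_id`
#' column, glucose columns `g0`, `g30`, `g60`, `g90`, `g120` (mmol/l at
#' the canonical minutes after glucose load), and optional covariates
#' `bmi` (kg/m^2), `bmi_category` (underweight/normal/overweight/obese)
#' and `outcome_2h_late` (2-h glucose later in pregnancy, mmol/l).
#' Missing measurements are `NA`, never sentinel numbers. Provenance
#' (source file, seed, filters) is carried in the `"metadata"` attribute.
#'
#' @param data A data frame with at least `subject_id` and the five
#'   glucose columns.
#' @param metadata Named list of provenance fields.
#' @return The data frame with class `ogtt_cohort` prepended.
#' @export
ogtt_cohort <- function(data, metadata = list()) {
  need <- c("subject_id", glucose_cols())
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(data$subject_id))
    stop("subject_id values must be unique within a cohort")
  for (cl in glucose_cols()) {
    v <- data[[cl]]
    if (!is.numeric(v))
      stop("glucose column '", cl, "' is not numeric")
    bad <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad))
      stop("glucose column '", cl, "' has non-positive or non-finite ",
           "value(s) at row(s) ", paste(head(bad, 5L), collapse = ", "))
  }
  structure(as.data.frame(data), metadata = metadata,
            class = c("ogtt_cohort", "data.frame"))
}

#' Read an OGTT cohort from CSV
#'
#' Two layouts are supported. `wide`: one row per subject with columns
#' `subject_id`, `g0`, `g30`, `g60`, `g90`, `g120` plus any covariate
#' columns. `long`: columns `subject_id`, `time_min`, `glucose_mmol_l`,
#' one row per measurement; times must belong to the canonical grid
#' \{0, 30, 60, 90, 120\} (the study design has exactly five samples).
#' Empty cells and `NA` tokens become missing values.
#'
#' @param path CSV file with a header row.
#' @param layout `"wide"` or `"long"`.
#' @param covariates Optional CSV of per-subject covariates keyed by
#'   `subject_id`, merged onto the cohort.
#' @return An [ogtt_cohort()].
#' @export
read_ogtt_cohort <- function(path, layout = c("wide", "long"),
                             covariates = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))

  if (layout == "wide") {
    need <- c("subject_id", glucose_cols())
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("malformed header in '", path, "': missing column(s) ",
           paste(miss, collapse = ", "))
    for (cl in glucose_cols()) raw[[cl]] <- parse_glucose(raw[[cl]], cl)
    wide <- raw
  } else {
    need <- c("subject_id", "time_min", "glucose_mmol_l")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      stop("malformed header in '", path, "': missing column(s) ",
           paste(miss, collapse = ", "))
    raw$glucose_mmol_l <- parse_glucose(raw$glucose_mmol_l, "glucose_mmol_l")
    bad <- !raw$time_min %in% ogtt_times()
    if (any(bad))
      stop("non-canonical time_min value(s) in '", path, "': ",
           paste(unique(raw$time_min[bad]), collapse = ", "),
           "; the design has exactly five samples at 0/30/60/90/120 min")
    ids <- unique(raw$subject_id)
    wide <- data.frame(subject_id = ids)
    for (tm in ogtt_times()) {
      cl <- paste0("g", tm)
      sub <- raw[raw$time_min == tm, ]
      if (anyDuplicated(sub$subject_id))
        stop("duplicate measurement at ", tm, " min for subject(s) ",
             paste(unique(sub$subject_id[duplicated(sub$subject_id)]),
                   collapse = ", "))
      wide[[cl]] <- sub$glucose_mmol_l[match(ids, sub$subject_id)]
    }
    extra <- setdiff(names(raw), need)
    for (cl in extra)
      wide[[cl]] <- raw[[cl]][match(ids, raw$subject_id)]
  }

  if (!is.null(covariates)) {
    cov <- read.csv(covariates, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
    if (!"subject_id" %in% names(cov))
      stop("covariates file lacks a subject_id column")
    wide <- merge(wide, cov, by = "subject_id", all.x = TRUE, sort = FALSE)
  }
  ogtt_cohort(wide, metadata = list(source = path, layout = layout))
}

# numeric parse with row-indexed errors; NA passes through
parse_glucose <- function(x, colname) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop("non-numeric glucose in column '", colname, "' at row(s) ",
         paste(head(bad, 5L), collapse = ", "))
  out
}

#' Write a cohort to CSV
#'
#' Round-trips through [read_ogtt_cohort()]: writing then reading yields
#' a field-by-field identical cohort.
#'
#' @param cohort An [ogtt_cohort()].
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"` (long drops covariate columns into
#'   repeated per-row values).
#' @return `path`, invisibly.
#' @export
write_ogtt_cohort <- function(cohort, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "wide") {
    write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "NA")
  } else {
    long <- do.call(rbind, lapply(ogtt_times(), function(tm) {
      data.frame(subject_id = cohort$subject_id, time_min = tm,
                 glucose_mmol_l = cohort[[paste0("g", tm)]])
    }))
    long <- long[order(match(long$subject_id, cohort$subject_id)), ]
    write.csv(long, path, row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Restrict a cohort to complete OGTT records
#'
#' A record is complete when all five canonical measurements are present.
#' Subjects with any missing glucose value are excluded, mirroring the
#' usual handling of incomplete tolerance tests in cohort studies.
#'
#' @param cohort An [ogtt_cohort()].
#' @return A list with `cohort` (the retained records, an `ogtt_cohort`),
#'   `exclusions` (data frame of excluded `subject_id` and their missing
#'   times) and `report` (named list: `n_input`, `n_retained`,
#'   `n_excluded`, `pct_excluded` — the exclusion percentage rounded to
#'   one decimal).
#' @export
filter_complete <- function(cohort) {
  stopifnot(inherits(cohort, "ogtt_cohort"))
  G <- as.matrix(as.data.frame(cohort)[, glucose_cols()])
  ok <- rowSums(is.na(G)) == 0L
  excl <- data.frame(subject_id = cohort$subject_id[!ok],
                     missing_times = vapply(which(!ok), function(i) {
                       paste(ogtt_times()[is.na(G[i, ])], collapse = ";")
                     }, character(1L)))
  meta <- attr(cohort, "metadata")
  meta$filter <- "complete OGTT"
  meta$n_excluded <- sum(!ok)
  retained <- ogtt_cohort(as.data.frame(cohort)[ok, , drop = FALSE],
                          metadata = meta)
  report <- list(n_input = nrow(cohort), n_retained = sum(ok),
                 n_excluded = sum(!ok),
                 pct_excluded = round(100 * sum(!ok) / max(1L, nrow(cohort)),
                                      1))
  list(cohort = retained, exclusions = excl, report = report)
}

#' Percentage rounded as reported in cohort descriptions
#'
#' Plain rounding of `100 * num / den` to `digits` decimals, the
#' convention used for cohort bookkeeping (exclusion fractions,
#' follow-up availability, prevalence).
#'
#' @param num,den Counts.
#' @param digits Decimals; default 1.
#' @return Numeric percentage.
#' @export
pct <- function(num, den, digits = 1) round(100 * num / den, digits)

#' Compare two cohorts on baseline variables
#'
#' Continuous variables are compared by two-sample t tests, categorical
#' variables by chi-square tests. A variable with zero variance in both
#' groups yields an undefined (NA) test rather than an error.
#'
#' @param a,b Two [ogtt_cohort()]s (or plain data frames).
#' @param variables Column names present in both.
#' @return Data frame: variable, type, statistic, p.
#' @export
compare_groups <- function(a, b, variables) {
  miss <- setdiff(variables, intersect(names(a), names(b)))
  if (length(miss))
    stop("variable(s) not present in both cohorts: ",
         paste(miss, collapse = ", "))
  rows <- lapply(variables, function(v) {
    x <- a[[v]]; y <- b[[v]]
    if (is.numeric(x) && is.numeric(y)) {
      if (isTRUE(var(x, na.rm = TRUE) == 0) &&
          isTRUE(var(y, na.rm = TRUE) == 0))
        return(data.frame(variable = v, type = "continuous",
                          statistic = NA_real_, p = NA_real_))
      tt <- t.test(x, y)
      data.frame(variable = v, type = "continuous",
                 statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      tab <- table(factor(c(rep("a", length(x)), rep("b", length(y)))),
                   c(as.character(x), as.character(y)))
      if (ncol(tab) < 2L)
        return(data.frame(variable = v, type = "categorical",
                          statistic = NA_real_, p = NA_real_))
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      data.frame(variable = v, type = "categorical",
                 statistic = unname(ct$statistic), p = ct$p.value)
    }
  })
  do.call(rbind, rows)
}

#' Glucose measurement matrix of a complete cohort
#'
#' @param cohort An [ogtt_cohort()] with no missing glucose values
#'   (apply [filter_complete()] first).
#' @return J x n numeric matrix (rows = canonical times, columns =
#'   subjects, column names = subject ids) ready for [fit_ogtt_curves()].
#' @export
cohort_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "ogtt_cohort"))
  G <- t(as.matrix(as.data.frame(cohort)[, glucose_cols()]))
  if (anyNA(G))
    stop("cohort has incomplete records; apply filter_complete() first")
  rownames(G) <- ogtt_times()
  colnames(G) <- cohort$subject_id
  G
}

#' @export
print.ogtt_cohort <- function(x, ...) {
  G <- as.matrix(as.data.frame(x)[, glucose_cols()])
  cat("OGTT cohort:", nrow(x), "subjects,",
      sum(rowSums(is.na(G)) == 0L), "with complete five-point tests\n")
  covs <- setdiff(names(x), c("subject_id", glucose_cols()))
  if (length(covs)) cat("covariates:", paste(covs, collapse = ", "), "\n")
  invisible(x)
}
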