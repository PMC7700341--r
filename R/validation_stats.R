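#' Kruskal-Wallis rank test
#'
#' Thin, validated surface over [stats::kruskal.test()]: midranks with the
#' standard tie correction, p-value from the chi-square distribution with
#' k - 1 degrees of freedom. The degenerate all-values-identical case (tie
#' correction denominator zero) is returned as `H = 0`, `p = 1` — an
#' exchangeable sample carries no evidence of a location difference.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List: `H` (statistic), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("all groups must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (any(is.na(values))) stop("missing values are not allowed; subset first")
  if (length(values) < 5L) stop("need a total of at least 5 observations")
  df <- length(groups) - 1L
  if (length(unique(values)) == 1L) return(list(H = 0, df = df, p = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Median and interquartile descriptives
#'
#' Quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7, the package-wide convention); `IQR = Q3 - Q1`.
#'
#' @param values Non-empty numeric vector (`NA` dropped).
#' @return List: `n`, `median`, `q1`, `q3`, `iqr`.
#' @export
describe_quartiles <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to describe")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
}

#' Attrition comparisons between retained and dropped participants
#'
#' Pearson chi-square on the category-by-retention contingency table for
#' categorical variables; Welch two-sample t-test for continuous ones.
#' Variables with a single observed level (or too few observations) are
#' skipped with a reason.
#'
#' @param retained,dropped Data frames sharing the compared columns.
#' @param types Named character vector mapping each compared variable to
#'   `"categorical"` or `"continuous"`.
#' @param alpha Flagging level (default 0.05).
#' @return Data frame: `variable`, `type`, `statistic`, `p`, `flagged`,
#'   `note`.
#' @export
attrition_tests <- function(retained, dropped, types, alpha = 0.05) {
  stopifnot(is.data.frame(retained), is.data.frame(dropped))
  rows <- lapply(names(types), function(v) {
    ty <- match.arg(types[[v]], c("categorical", "continuous"))
    x <- retained[[v]]; y <- dropped[[v]]
    if (is.null(x) || is.null(y))
      return(data.frame(variable = v, type = ty, statistic = NA_real_,
                        p = NA_real_, flagged = NA, note = "variable missing"))
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (ty == "continuous") {
      if (length(x) < 2L || length(y) < 2L || (stats::sd(x) == 0 && stats::sd(y) == 0))
        return(data.frame(variable = v, type = ty, statistic = NA_real_,
                          p = NA_real_, flagged = NA, note = "degenerate"))
      tt <- stats::t.test(x, y, var.equal = FALSE)
      data.frame(variable = v, type = ty, statistic = unname(tt$statistic),
                 p = tt$p.value, flagged = tt$p.value <= alpha, note = "")
    } else {
      tab <- table(retention = rep(c("retained", "dropped"),
                                   c(length(x), length(y))),
                   level = c(as.character(x), as.character(y)))
      if (ncol(tab) < 2L)
        return(data.frame(variable = v, type = ty, statistic = NA_real_,
                          p = NA_real_, flagged = NA, note = "single observed level"))
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, type = ty, statistic = unname(ct$statistic),
                 p = ct$p.value, flagged = ct$p.value <= alpha, note = "")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-group criterion-validity report
#'
#' For each outcome column, complete cases are split by the score group and
#' summarized as median/IQR per group with a Kruskal-Wallis test (two groups,
#' 1 df). Outcomes leaving fewer than 2 observations in either group are
#' reported untested. An optional one-way ANOVA p-value per outcome is
#' appended as a parametric cross-check (never a decision rule).
#'
#' @param groups Output of [assign_group()] (`dyad_id`, `group`).
#' @param outcomes Data frame with `dyad_id` and one column per outcome.
#' @param alpha Significance level recorded in the report (default 0.05).
#' @param anova_check Add an `anova_p` cross-check column (default `FALSE`).
#' @return Data frame of class `validation_report`: per outcome `n_low`,
#'   `median_low`, `iqr_low`, `q1_low`, `q3_low`, the same for the high
#'   group, `H`, `p`, `significant`, `tested`.
#' @export
validation_report <- function(groups, outcomes, alpha = 0.05,
                              anova_check = FALSE) {
  stopifnot(all(c("dyad_id", "group") %in% names(groups)))
  stopifnot("dyad_id" %in% names(outcomes))
  idx <- match(groups$dyad_id, outcomes$dyad_id)
  rows <- lapply(setdiff(names(outcomes), "dyad_id"), function(oc) {
    y <- outcomes[[oc]][idx]
    ok <- !is.na(y)
    lo <- y[ok & groups$group == "low"]
    hi <- y[ok & groups$group == "high"]
    row <- data.frame(outcome = oc, n_low = length(lo), median_low = NA_real_,
                      iqr_low = NA_real_, q1_low = NA_real_, q3_low = NA_real_,
                      n_high = length(hi), median_high = NA_real_,
                      iqr_high = NA_real_, q1_high = NA_real_, q3_high = NA_real_,
                      H = NA_real_, p = NA_real_, significant = NA,
                      tested = FALSE, stringsAsFactors = FALSE)
    if (length(lo) >= 1L) {
      d <- describe_quartiles(lo)
      row[c("median_low", "iqr_low", "q1_low", "q3_low")] <-
        list(d$median, d$iqr, d$q1, d$q3)
    }
    if (length(hi) >= 1L) {
      d <- describe_quartiles(hi)
      row[c("median_high", "iqr_high", "q1_high", "q3_high")] <-
        list(d$median, d$iqr, d$q1, d$q3)
    }
    if (length(lo) >= 2L && length(hi) >= 2L) {
      kw <- kruskal_wallis(list(low = lo, high = hi))
      row$H <- kw$H; row$p <- kw$p
      row$significant <- kw$p <= alpha
      row$tested <- TRUE
      if (anova_check) {
        g <- factor(rep(c("low", "high"), c(length(lo), length(hi))))
        row$anova_p <- stats::anova(stats::lm(c(lo, hi) ~ g))[["Pr(>F)"]][1]
      }
    } else if (anova_check) {
      row$anova_p <- NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Run the full scoring-to-validation pipeline on a cohort
#'
#' Ties all modules together: totals the instrument over `items`
#' ([score_total()]), dichotomizes complete respondents at `threshold`
#' ([assign_group()]), derives anthropometric outcomes ([derive_anthro()]),
#' runs lab QC and the composite indices ([process_lab()], [build_indices()]),
#' and tests every outcome between the two score groups
#' ([validation_report()]).
#'
#' @param cohort List with tables `responses`, `anthro`, `replicates`,
#'   `plate_controls`, `chemistry` (the layout produced by
#'   [simulate_cohort()]; real data in the same layout works identically).
#' @param cb Instrument codebook.
#' @param items Item ids forming the scored instrument.
#' @param threshold Dichotomization cut point (default 75).
#' @param index_specs Index definitions (default [default_index_specs()]).
#' @param scaling Optional index-scaling override (`"zsum"`/`"tscore"`).
#' @param lms_ref LMS reference for the anthropometry (default packaged
#'   synthetic table).
#' @param alpha Significance level (default 0.05).
#' @param anova_check Append the ANOVA cross-check column (default `FALSE`).
#' @return List: `report` (a `validation_report` over BMI percentile, BMI z,
#'   waist-to-height ratio and the indices), `groups`, `anthro_derived`,
#'   `panel`, `indices`.
#' @export
run_validation <- function(cohort, cb, items, threshold = 75,
                           index_specs = default_index_specs(),
                           scaling = NULL, lms_ref = load_lms_reference(),
                           alpha = 0.05, anova_check = FALSE) {
  totals <- score_total(cohort$responses, cb, items)
  groups <- assign_group(totals, threshold = threshold)
  anthro <- derive_anthro(cohort$anthro, lms_ref = lms_ref)
  lab <- process_lab(cohort$replicates, cohort$plate_controls,
                     chemistry = cohort$chemistry)
  indices <- build_indices(lab$panel, specs = index_specs, scaling = scaling)
  outcomes <- data.frame(dyad_id = anthro$dyad_id,
                         bmi_percentile = anthro$bmi_percentile,
                         bmi_z = anthro$bmi_z, whtr = anthro$whtr,
                         stringsAsFactors = FALSE)
  for (nm in setdiff(names(indices), "dyad_id")) {
    outcomes[[nm]] <- indices[[nm]][match(outcomes$dyad_id, indices$dyad_id)]
  }
  # dyads with biomarkers but no anthropometry still contribute to the indices
  extra <- setdiff(indices$dyad_id, outcomes$dyad_id)
  if (length(extra)) {
    add <- outcomes[rep(NA_integer_, length(extra)), ]
    add$dyad_id <- extra
    for (nm in setdiff(names(indices), "dyad_id"))
      add[[nm]] <- indices[[nm]][match(extra, indices$dyad_id)]
    outcomes <- rbind(outcomes, add)
  }
  report <- validation_report(groups, outcomes, alpha = alpha,
                              anova_check = anova_check)
  list(report = report, groups = groups, anthro_derived = anthro,
       panel = lab$panel, indices = indices)
}
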