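#' Replicate selection by coefficient of variation
#'
#' Immunoassay replicate QC. If the CV (sample SD / mean) of all replicates is
#' below `cv_threshold` the mean of all is reported (`ok`). Otherwise, for
#' triplicates, the pair with the smallest CV is chosen; if that pair passes
#' the threshold the flag is `best_pair`, else the best pair's mean is still
#' reported but flagged `fail` (values are retained, never silently dropped;
#' exclusion is left to the caller). Duplicates that fail are flagged `fail`
#' directly. Ties in pair CV are broken toward the larger pair mean, which
#' keeps the choice invariant to replicate order.
#'
#' @param values Numeric vector of 2-3 nonnegative replicate measurements.
#' @param cv_threshold CV acceptance bound as a fraction (default 0.05; assays
#'   with a looser spec, e.g. IGFBP-1 at 10%, pass their own bound).
#' @return List with `value` (reported concentration), `cv` (of the reported
#'   set) and `flag` (`"ok"`, `"best_pair"` or `"fail"`).
#' @export
select_replicates <- function(values, cv_threshold = 0.05) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 2L) stop("need at least 2 replicates")
  if (length(values) > 3L) stop("more than 3 replicates are not supported")
  if (any(values < 0) || any(!is.finite(values))) stop("replicates must be finite and >= 0")
  cv_all <- replicate_cv(values)
  if (cv_all < cv_threshold)
    return(list(value = mean(values), cv = cv_all, flag = "ok"))
  if (length(values) == 2L)
    return(list(value = mean(values), cv = cv_all, flag = "fail"))
  pairs <- list(values[c(1, 2)], values[c(1, 3)], values[c(2, 3)])
  cvs <- vapply(pairs, replicate_cv, numeric(1))
  means <- vapply(pairs, mean, numeric(1))
  best <- order(cvs, -means)[1]
  flag <- if (cvs[best] < cv_threshold) "best_pair" else "fail"
  list(value = means[best], cv = cvs[best], flag = flag)
}

# CV = sample SD / mean; a zero-mean, zero-spread set has CV 0
replicate_cv <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(0)
  if (m == 0) return(Inf)
  s / m
}

#' Internal-control plate normalization
#'
#' Removes plate-to-plate variability of an immunoassay analyte using the
#' internal control run on every plate, under a multiplicative error model:
#' each value is scaled by `geometric mean(all plate controls) / control of
#' its own plate`. Plates whose control sits above the global geometric mean
#' are scaled down, and the correction factors multiply to one across plates.
#'
#' @param values Named numeric vector of per-dyad values for one analyte.
#' @param plate_ids Character vector (same length/order) giving each value's
#'   plate.
#' @param controls Named numeric vector mapping plate id to its positive
#'   control value; every plate present in `plate_ids` must appear.
#' @return Adjusted values (same names/order).
#' @export
plate_normalize <- function(values, plate_ids, controls) {
  stopifnot(length(values) == length(plate_ids))
  plate_ids <- as.character(plate_ids)
  if (is.null(names(controls))) stop("controls must be named by plate id")
  missing_ctrl <- setdiff(unique(plate_ids), names(controls))
  if (length(missing_ctrl))
    stop("no control for plate(s): ", paste(missing_ctrl, collapse = ", "))
  if (any(!is.finite(controls)) || any(controls <= 0))
    stop("controls must be positive")
  gm <- exp(mean(log(controls)))
  values * gm / unname(controls[plate_ids])
}

#' Tukey-fence outlier flags
#'
#' Flags values beyond 1.5 interquartile ranges outside the quartiles
#' (`x > Q3 + 1.5*IQR` or `x < Q1 - 1.5*IQR`). Quartiles use linear
#' interpolation between order statistics (`stats::quantile` type 7), the
#' convention used throughout the package.
#'
#' @param values Numeric vector, at least 4 non-missing values.
#' @return Logical vector, `TRUE` where the value is an outlier (`NA` in,
#'   `NA` out).
#' @export
flag_outliers <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) stop("need at least 4 values to place Tukey fences")
  q <- stats::quantile(values[ok], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  flags <- values < q[1] - 1.5 * iqr | values > q[2] + 1.5 * iqr
  flags
}

#' Derived biomarkers from the measured panel
#'
#' Adds, per child and only where the inputs are present:
#' * `ldl_c` (mg/dL) by Friedewald: total cholesterol - HDL-C - TG/5, withheld
#'   (with `friedewald_valid = FALSE`) when TG >= 400 mg/dL;
#' * `non_hdl_c` = total cholesterol - HDL-C;
#' * `homa_ir` = insulin (uIU/mL) x glucose (mmol/L) / 22.5, glucose converted
#'   from mg/dL by the factor 0.0555;
#' * `chol_hdl_ratio`, `tg_hdl_ratio`;
#' * `leptin_adiponectin_ratio` with adiponectin harmonized from ug/mL to
#'   ng/mL (x1000) to match leptin's ng/mL.
#' Ratios with a zero denominator are withheld.
#'
#' @param panel Data frame with `dyad_id` and any of `glucose`, `insulin`,
#'   `leptin`, `adiponectin`, `triglycerides`, `total_cholesterol`, `hdl_c`
#'   (units as in the field list above); missing entries `NA`.
#' @return `panel` with the derived columns and `friedewald_valid` appended.
#' @export
derive_panel <- function(panel) {
  stopifnot(is.data.frame(panel), "dyad_id" %in% names(panel))
  get <- function(nm) if (nm %in% names(panel)) panel[[nm]] else rep(NA_real_, nrow(panel))
  tc <- get("total_cholesterol"); hdl <- get("hdl_c"); tg <- get("triglycerides")
  glucose <- get("glucose"); insulin <- get("insulin")
  leptin <- get("leptin"); adiponectin <- get("adiponectin")
  for (v in list(tc, hdl, tg, glucose, insulin, leptin, adiponectin))
    if (any(v < 0, na.rm = TRUE)) stop("biomarker values must be nonnegative")

  out <- panel
  out$friedewald_valid <- ifelse(is.na(tg), NA, tg < 400)
  out$ldl_c <- ifelse(!is.na(tc) & !is.na(hdl) & !is.na(tg) & tg < 400,
                      tc - hdl - tg / 5, NA_real_)
  out$non_hdl_c <- tc - hdl
  out$homa_ir <- insulin * (glucose * 0.0555) / 22.5
  out$chol_hdl_ratio <- ifelse(!is.na(hdl) & hdl > 0, tc / hdl, NA_real_)
  out$tg_hdl_ratio <- ifelse(!is.na(hdl) & hdl > 0, tg / hdl, NA_real_)
  adi_ng <- adiponectin * 1000  # ug/mL -> ng/mL
  out$leptin_adiponectin_ratio <- ifelse(!is.na(adi_ng) & adi_ng > 0,
                                         leptin / adi_ng, NA_real_)
  out
}

#' Immunoassay analytes and their CV bounds
#'
#' Default per-analyte replicate-CV acceptance thresholds: 5% for all
#' immunoassay analytes except IGFBP-1 (10%).
#' @return Named numeric vector of CV thresholds.
#' @export
default_cv_thresholds <- function() {
  c(insulin = 0.05, leptin = 0.05, adiponectin = 0.05, igfbp1 = 0.10,
    il10 = 0.05, crp = 0.05, resistin = 0.05)
}

#' Run the full lab QC pipeline
#'
#' Per (dyad, analyte): replicate selection by CV, then internal-control plate
#' normalization, assembled into a wide per-dyad biomarker panel; clinical-
#' chemistry analytes (single determinations, no plates) are merged in and
#' the derived biomarkers appended via [derive_panel()]. Tukey-fence outlier
#' flags per analyte are reported, never removed.
#'
#' @param replicates Data frame `dyad_id`, `analyte`, `plate_id`, `rep1`,
#'   `rep2`, `rep3` (rep3 `NA` for duplicate assays).
#' @param controls Data frame `analyte`, `plate_id`, `value` of internal
#'   controls.
#' @param chemistry Optional data frame `dyad_id` plus single-determination
#'   columns (`glucose`, `triglycerides`, `total_cholesterol`, `hdl_c`).
#' @param cv_thresholds Named per-analyte CV bounds; see
#'   [default_cv_thresholds()].
#' @return List: `panel` (wide per-dyad panel with derived columns), `qc`
#'   (long per dyad-analyte QC record: value, cv, flag, outlier).
#' @export
process_lab <- function(replicates, controls, chemistry = NULL,
                        cv_thresholds = default_cv_thresholds()) {
  stopifnot(is.data.frame(replicates),
            all(c("dyad_id", "analyte", "plate_id", "rep1", "rep2") %in% names(replicates)))
  stopifnot(is.data.frame(controls),
            all(c("analyte", "plate_id", "value") %in% names(controls)))
  reps <- as.matrix(replicates[, intersect(c("rep1", "rep2", "rep3"),
                                           names(replicates)), drop = FALSE])
  qc <- replicates[, c("dyad_id", "analyte", "plate_id")]
  picked <- lapply(seq_len(nrow(reps)), function(i) {
    thr <- cv_thresholds[[qc$analyte[i]]] %||% 0.05
    select_replicates(reps[i, ], cv_threshold = thr)
  })
  qc$value <- vapply(picked, `[[`, numeric(1), "value")
  qc$cv <- vapply(picked, `[[`, numeric(1), "cv")
  qc$flag <- vapply(picked, `[[`, character(1), "flag")

  qc$adjusted <- NA_real_
  qc$outlier <- NA
  for (an in unique(qc$analyte)) {
    sel <- qc$analyte == an
    ctrl <- controls[controls$analyte == an, ]
    cvec <- stats::setNames(ctrl$value, ctrl$plate_id)
    qc$adjusted[sel] <- plate_normalize(qc$value[sel], qc$plate_id[sel], cvec)
    if (sum(sel) >= 4L) qc$outlier[sel] <- flag_outliers(qc$adjusted[sel])
  }

  dyads <- unique(c(qc$dyad_id, if (!is.null(chemistry)) chemistry$dyad_id))
  panel <- data.frame(dyad_id = dyads, stringsAsFactors = FALSE)
  for (an in unique(qc$analyte)) {
    sel <- qc$analyte == an
    panel[[an]] <- qc$adjusted[sel][match(dyads, qc$dyad_id[sel])]
  }
  if (!is.null(chemistry)) {
    stopifnot("dyad_id" %in% names(chemistry))
    for (cn in setdiff(names(chemistry), "dyad_id"))
      panel[[cn]] <- chemistry[[cn]][match(dyads, chemistry$dyad_id)]
  }
  list(panel = derive_panel(panel), qc = qc)
}
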