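#' z-standardize a column
#'
#' Centers and scales with the sample (n-1) standard deviation over the
#' non-missing values; `NA`s stay `NA`.
#'
#' @param x Numeric vector with at least 2 distinct non-missing values.
#' @return List: `z` (same length as `x`), `mean`, `sd`.
#' @export
zstandardize <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least 2 values to standardize")
  m <- mean(x[ok])
  s <- stats::sd(x[ok])
  if (s == 0) stop("zero variance: column cannot be standardized")
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Define a composite biomarker index
#'
#' @param name Index name.
#' @param components Character vector of panel column names (>= 2).
#' @param signs Vector of +1/-1, one per component: -1 flips a component whose
#'   raw association runs against the index's direction (e.g. HDL-C in a lipid
#'   risk index).
#' @param scaling `"zsum"` (sum of signed z-scores) or `"tscore"` (sum of
#'   per-component T-scores `50 + 10 * sign * z`).
#' @return Object of class `index_spec`.
#' @export
index_spec <- function(name, components, signs = rep(1, length(components)),
                       scaling = c("zsum", "tscore")) {
  scaling <- match.arg(scaling)
  stopifnot(is.character(components), length(components) >= 2L)
  if (length(signs) != length(components)) stop("one sign per component")
  if (!all(signs %in% c(-1, 1))) stop("signs must be +1 or -1")
  if (anyDuplicated(components)) stop("duplicate components")
  structure(list(name = name, components = components,
                 signs = as.numeric(signs), scaling = scaling),
            class = "index_spec")
}

#' @export
print.index_spec <- function(x, ...) {
  cat("index '", x$name, "' (", x$scaling, "): ",
      paste0(ifelse(x$signs < 0, "-", "+"), x$components, collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' The three default composite indices
#'
#' Metabolic: glucose, insulin, leptin, leptin:adiponectin, TG:HDL-C and
#' HOMA-IR, all entering positively. Lipid: LDL-C, non-HDL-C,
#' cholesterol:HDL-C and triglycerides positive, HDL-C negated (its
#' association with lipid risk is inverse). Anti-inflammatory: adiponectin,
#' IGFBP-1 and IL-10 positive, CRP and resistin negated (pro-inflammatory).
#'
#' @param scaling Scaling mode applied to all three (default `"zsum"`).
#' @return Named list of three [index_spec()] objects.
#' @export
default_index_specs <- function(scaling = c("zsum", "tscore")) {
  scaling <- match.arg(scaling)
  list(
    metabolic = index_spec(
      "metabolic",
      c("glucose", "insulin", "leptin", "leptin_adiponectin_ratio",
        "tg_hdl_ratio", "homa_ir"),
      signs = c(1, 1, 1, 1, 1, 1), scaling = scaling),
    lipid = index_spec(
      "lipid",
      c("hdl_c", "ldl_c", "non_hdl_c", "chol_hdl_ratio", "triglycerides"),
      signs = c(-1, 1, 1, 1, 1), scaling = scaling),
    anti_inflammatory = index_spec(
      "anti_inflammatory",
      c("adiponectin", "igfbp1", "il10", "crp", "resistin"),
      signs = c(1, 1, 1, -1, -1), scaling = scaling)
  )
}

#' Build a composite index over a biomarker panel
#'
#' Each component column is z-standardized over the dyads where it is present
#' (complete-case per component, so every component uses its full available
#' n), then combined as `sum(sign * z)` (`zsum`) or `sum(50 + 10 * sign * z)`
#' (`tscore`). A dyad receives an index value only when all components are
#' present; the two scalings are affinely equivalent and rank dyads
#' identically.
#'
#' @param panel Wide per-dyad panel (e.g. `process_lab()$panel`).
#' @param spec An [index_spec()].
#' @param scaling Optional override of `spec$scaling`.
#' @param standardize `"per_component"` (default): each component is
#'   standardized over all dyads where it is present, so every component uses
#'   its full n; `"complete_case"`: standardization restricted to dyads with
#'   every component present, making the zsum index mean exactly 0 (tscore
#'   mean exactly 50k) over that set.
#' @return Data frame `dyad_id`, `index`, `value`, `n_components_present`.
#' @export
build_index <- function(panel, spec, scaling = NULL,
                        standardize = c("per_component", "complete_case")) {
  stopifnot(inherits(spec, "index_spec"), is.data.frame(panel),
            "dyad_id" %in% names(panel))
  scaling <- scaling %||% spec$scaling
  standardize <- match.arg(standardize)
  missing_cols <- setdiff(spec$components, names(panel))
  if (length(missing_cols))
    stop("panel lacks component(s): ", paste(missing_cols, collapse = ", "))
  raw <- panel[, spec$components, drop = FALSE]
  std_set <- if (standardize == "complete_case")
    rowSums(is.na(raw)) == 0 else rep(TRUE, nrow(raw))
  zmat <- vapply(seq_along(spec$components), function(j) {
    x <- raw[[j]]
    zs <- zstandardize(ifelse(std_set, x, NA_real_))
    z <- (x - zs$mean) / zs$sd
    s <- spec$signs[j]
    if (scaling == "tscore") 50 + 10 * s * z else s * z
  }, numeric(nrow(panel)))
  zmat <- matrix(zmat, nrow = nrow(panel))
  all_present <- rowSums(is.na(zmat)) == 0
  data.frame(dyad_id = panel$dyad_id,
             index = spec$name,
             value = ifelse(all_present, rowSums(zmat), NA_real_),
             n_components_present = rowSums(!is.na(zmat)),
             stringsAsFactors = FALSE)
}

#' Build several indices into one wide table
#'
#' @param panel Wide per-dyad panel.
#' @param specs List of [index_spec()]s (default [default_index_specs()]).
#' @param scaling Optional scaling override applied to all.
#' @param standardize Standardization-set policy, see [build_index()].
#' @return Data frame `dyad_id` plus one column per index.
#' @export
build_indices <- function(panel, specs = default_index_specs(), scaling = NULL,
                          standardize = c("per_component", "complete_case")) {
  standardize <- match.arg(standardize)
  out <- data.frame(dyad_id = panel$dyad_id, stringsAsFactors = FALSE)
  for (spec in specs)
    out[[spec$name]] <- build_index(panel, spec, scaling = scaling,
                                    standardize = standardize)$value
  out
}
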