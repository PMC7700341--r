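#' Body mass index from weight and height
#'
#' @param weight_kg Weight in kilograms.
#' @param height_cm Height (stature) in centimetres. If repeated measures were
#'   taken they must be averaged before calling (see [derive_anthro()], which
#'   does this).
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(16, 100)   # 16
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)))
    stop("weight and height must be finite")
  if (any(weight_kg <= 0)) stop("weight must be positive")
  if (any(height_cm <= 0)) stop("height must be positive")
  weight_kg / (height_cm / 100)^2
}

#' LMS z-score transform
#'
#' Maps a measurement to a z-score against a growth reference parameterized by
#' the Box-Cox power `L`, median `M` and coefficient of variation `S`:
#' `z = ((x/M)^L - 1) / (L * S)`, with the continuous log limit
#' `z = log(x/M) / S` at `L = 0`.
#'
#' @param x Measurement (same units as `M`); must be positive.
#' @param L,M,S Reference parameters; `M > 0`, `S > 0`.
#' @return z-score in standard-deviation units.
#' @seealso [lms_inverse()] for the exact inverse.
#' @export
lms_z <- function(x, L, M, S) {
  if (any(!is.finite(x)) || any(x <= 0)) stop("x must be positive and finite")
  if (any(M <= 0) || any(S <= 0)) stop("M and S must be positive")
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  z <- numeric(n)
  zero <- abs(L) < 1e-12
  z[zero] <- log(x[zero] / M[zero]) / S[zero]
  z[!zero] <- ((x[!zero] / M[!zero])^L[!zero] - 1) / (L[!zero] * S[!zero])
  z
}

#' Inverse LMS transform
#'
#' Returns the measurement whose LMS z-score is `z`:
#' `M * (1 + L*S*z)^(1/L)`, or `M * exp(S*z)` at `L = 0`. Used by the
#' synthetic cohort generator to realize BMI values from simulated z-scores.
#'
#' @inheritParams lms_z
#' @param z z-score. For `L != 0` requires `1 + L*S*z > 0`.
#' @export
lms_inverse <- function(z, L, M, S) {
  if (any(!is.finite(z))) stop("z must be finite")
  if (any(M <= 0) || any(S <= 0)) stop("M and S must be positive")
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  x <- numeric(n)
  zero <- abs(L) < 1e-12
  x[zero] <- M[zero] * exp(S[zero] * z[zero])
  base <- 1 + L[!zero] * S[!zero] * z[!zero]
  if (any(base <= 0)) stop("z outside the valid domain: 1 + L*S*z must be positive")
  x[!zero] <- M[!zero] * base^(1 / L[!zero])
  x
}

#' Convert a z-score to a percentile
#'
#' Normal-CDF convention: `100 * pnorm(z)`.
#'
#' @param z z-score(s).
#' @return Percentile on the 0-100 scale.
#' @export
z_to_percentile <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  100 * stats::pnorm(z)
}

#' Weight category from a BMI-for-age percentile
#'
#' CDC cut points: obesity at or above the 95th percentile; overweight 85th to
#' less than the 95th; normal weight 5th to less than the 85th; underweight
#' below the 5th.
#'
#' @param percentile BMI-for-age percentile in `[0, 100]`.
#' @return Factor with levels `underweight`, `normal`, `overweight`, `obesity`.
#' @export
classify_weight <- function(percentile) {
  if (any(!is.finite(percentile)) || any(percentile < 0) || any(percentile > 100))
    stop("percentile must lie in [0, 100]")
  cut(percentile, breaks = c(-Inf, 5, 85, 95, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obesity"))
}

#' Waist-to-height ratio
#'
#' `100 * waist (cm) / height (cm)`, a percent-like central-adiposity proxy.
#'
#' @param waist_cm Waist circumference in cm.
#' @param height_cm Height in cm.
#' @export
waist_to_height <- function(waist_cm, height_cm) {
  if (any(!is.finite(waist_cm)) || any(waist_cm <= 0)) stop("waist must be positive")
  if (any(!is.finite(height_cm)) || any(height_cm <= 0)) stop("height must be positive")
  100 * waist_cm / height_cm
}

#' Load an LMS growth reference table
#'
#' Reads a delimited file with columns `sex`, `agemos`, `L`, `M`, `S` (the
#' layout used by the CDC growth-chart data files). The packaged reference at
#' `system.file("extdata", "lms_bmi_synthetic.csv", package = "kidrisk")` is a
#' synthetic-but-plausible BMI-for-age table covering 24-84 months for both
#' sexes, shipped so the package is testable without downloads; genuine CDC
#' tables in the same layout load identically.
#'
#' @param path File path; defaults to the packaged synthetic reference.
#' @param sep Field separator (default comma).
#' @return Data frame of class `lms_reference`, rows sorted by age within sex.
#' @export
load_lms_reference <- function(path = NULL, sep = ",") {
  if (is.null(path))
    path <- system.file("extdata", "lms_bmi_synthetic.csv", package = "kidrisk")
  stopifnot(file.exists(path))
  ref <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  names(ref) <- tolower(names(ref))
  names(ref)[names(ref) == "l"] <- "L"
  names(ref)[names(ref) == "m"] <- "M"
  names(ref)[names(ref) == "s"] <- "S"
  required <- c("sex", "agemos", "L", "M", "S")
  if (!all(required %in% names(ref)))
    stop("LMS reference must have columns sex, agemos, L, M, S")
  ref$sex <- normalize_sex(ref$sex)
  if (any(ref$M <= 0) || any(ref$S <= 0)) stop("M and S must be positive")
  ref <- ref[order(ref$sex, ref$agemos), required]
  for (sx in unique(ref$sex)) {
    ages <- ref$agemos[ref$sex == sx]
    if (any(diff(ages) <= 0)) stop("ages must be strictly increasing within sex")
  }
  rownames(ref) <- NULL
  class(ref) <- c("lms_reference", "data.frame")
  ref
}

normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female", "2")] <- "female"
  s[s %in% c("m", "male", "1")] <- "male"
  if (!all(s %in% c("female", "male"))) stop("sex must be female/male (or f/m, 2/1)")
  s
}

#' Interpolate LMS parameters at given sex and age
#'
#' L, M and S are interpolated linearly in age, separately per parameter,
#' within each sex; queries at a tabulated age return that row exactly.
#' Ages outside the table's span are an error.
#'
#' @param ref An `lms_reference` from [load_lms_reference()].
#' @param sex Vector of `"female"`/`"male"` (or `f`/`m`).
#' @param agemos Age in months.
#' @return Data frame with columns `L`, `M`, `S`, one row per query.
#' @export
lms_lookup <- function(ref, sex, agemos) {
  stopifnot(inherits(ref, "lms_reference"))
  sex <- normalize_sex(sex)
  n <- max(length(sex), length(agemos))
  sex <- rep_len(sex, n); agemos <- rep_len(agemos, n)
  out <- data.frame(L = numeric(n), M = numeric(n), S = numeric(n))
  for (sx in unique(sex)) {
    sub <- ref[ref$sex == sx, ]
    idx <- which(sex == sx)
    a <- agemos[idx]
    if (any(a < min(sub$agemos)) || any(a > max(sub$agemos)))
      stop("age outside the span of the LMS reference (", min(sub$agemos),
           "-", max(sub$agemos), " months)")
    for (p in c("L", "M", "S"))
      out[[p]][idx] <- stats::approx(sub$agemos, sub[[p]], xout = a)$y
  }
  out
}

#' Derive per-child anthropometric outcomes
#'
#' Averages repeat height/waist measures when present, then computes BMI,
#' the LMS BMI-for-age z-score and percentile, the CDC weight category and
#' the waist-to-height ratio.
#'
#' @param anthro Data frame with columns `dyad_id`, `sex`, `age_months`,
#'   `weight_kg`, and either `height_cm` or the repeat pair
#'   `height1_cm`/`height2_cm` (same for `waist_cm` / `waist1_cm`/`waist2_cm`).
#'   A repeat measure that is `NA` leaves the single available value in use.
#' @param lms_ref An `lms_reference`; defaults to the packaged synthetic table.
#' @return Data frame: `dyad_id`, `bmi`, `bmi_z`, `bmi_percentile`, `whtr`,
#'   `category`. Children with any missing input get `NA` outcomes.
#' @export
derive_anthro <- function(anthro, lms_ref = load_lms_reference()) {
  stopifnot(is.data.frame(anthro), "dyad_id" %in% names(anthro))
  height <- average_repeats(anthro, "height")
  waist <- average_repeats(anthro, "waist")
  weight <- anthro$weight_kg
  ok <- !is.na(height) & !is.na(waist) & !is.na(weight) &
    !is.na(anthro$age_months) & !is.na(anthro$sex)
  out <- data.frame(dyad_id = anthro$dyad_id, bmi = NA_real_, bmi_z = NA_real_,
                    bmi_percentile = NA_real_, whtr = NA_real_,
                    category = factor(rep(NA, nrow(anthro)),
                                      levels = c("underweight", "normal",
                                                 "overweight", "obesity")),
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    bmi <- compute_bmi(weight[ok], height[ok])
    lms <- lms_lookup(lms_ref, anthro$sex[ok], anthro$age_months[ok])
    z <- lms_z(bmi, lms$L, lms$M, lms$S)
    pct <- z_to_percentile(z)
    out$bmi[ok] <- bmi
    out$bmi_z[ok] <- z
    out$bmi_percentile[ok] <- pct
    out$whtr[ok] <- waist_to_height(waist[ok], height[ok])
    out$category[ok] <- classify_weight(pct)
  }
  out
}

# Average the "<base>1_cm"/"<base>2_cm" repeat pair if present, else take
# "<base>_cm". NA in one repeat falls back to the other.
average_repeats <- function(df, base) {
  r1 <- paste0(base, "1_cm"); r2 <- paste0(base, "2_cm"); single <- paste0(base, "_cm")
  if (r1 %in% names(df) && r2 %in% names(df)) {
    rowMeans(cbind(df[[r1]], df[[r2]]), na.rm = TRUE) -> m
    m[is.nan(m)] <- NA_real_
    m
  } else if (single %in% names(df)) {
    df[[single]]
  } else {
    stop("anthro table needs ", single, " or ", r1, "/", r2)
  }
}
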