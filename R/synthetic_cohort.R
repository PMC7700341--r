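#' Default 45-item instrument codebook
#'
#' A synthetic pool of 45 picture-book style items across 10 behavioural
#' constructs (9 fruit/vegetable items, 3 beans, 4 dairy, 4 whole grains,
#' 5 sugary drinks, 4 fast food, 4 snack foods, 4 eating habits, 4 screen
#' time, 4 activity & sleep). Every item is coded on a 5-point scale with the
#' highest score the healthiest behaviour; every third item carries
#' half-point option scores (sub-scored response sets), which is what puts
#' instrument totals on the half-point grid.
#'
#' @return A `codebook` with items `item01` ... `item45`.
#' @export
default_codebook <- function() {
  constructs <- rep(c("Fruits & Vegetables", "Beans", "Dairy", "Whole Grains",
                      "Sugary Drinks", "Fast Food", "Snack Foods",
                      "Eating Habits", "Screen Time", "Activity & Sleep"),
                    times = c(9, 3, 4, 4, 5, 4, 4, 4, 4, 4))
  items <- lapply(seq_along(constructs), function(i) {
    scores <- if (i %% 3 == 0) c(1, 2, 3, 3.5, 4.5) else c(1, 2, 3, 4, 5)
    names(scores) <- c("never", "rarely", "sometimes", "often", "always")
    item_def(sprintf("item%02d", i), constructs[i],
             sprintf("Healthful behaviour prompt %02d (%s)", i, constructs[i]),
             scores)
  })
  codebook(items, version_tag = "synthetic-pool-45")
}

#' Default informative-item subset
#'
#' Picks `k` items spread across constructs (round-robin by within-construct
#' position, lexicographic within rounds) — the generator's ground truth for
#' which items load on the latent adiposity factor, and the fixed instrument
#' scored by the end-to-end pipeline.
#'
#' @param cb A codebook (default [default_codebook()]).
#' @param k Number of informative items (default 18).
#' @return Character vector of item ids, sorted.
#' @export
default_informative_items <- function(cb = default_codebook(), k = 18) {
  ids <- item_ids(cb)
  cons <- vapply(cb$items, `[[`, character(1), "construct")
  rank_in_construct <- stats::ave(seq_along(ids), cons, FUN = seq_along)
  sort(ids[order(rank_in_construct, ids)][seq_len(k)])
}

#' Simulation configuration for a synthetic dyad cohort
#'
#' Defaults emulate the reference study's shape: 273 enrolled dyads with 206
#' expected to complete, 45 pool items with 18 informative ones whose scores
#' concentrate in response options 3-4 (totals roughly 51-81 on the
#' half-point grid), anthropometry missing on ~6 completers, ~190 blood
#' donors with clustered per-assay missingness leaving ~160 observations per
#' biomarker, 7 immunoassay plates with multiplicative plate effects and
#' internal controls, and replicate CVs around 4%. `effect_beta` is the
#' latent slope from the (standardized) instrument signal to the child's BMI
#' z-score, sign such that a higher score predicts lower BMI;
#' `biomarker_loadings` carry each analyte's signed correlation with BMI z
#' (positive for metabolic/lipid risk markers, negative for HDL-C and the
#' anti-inflammatory analytes).
#'
#' @param n_enrolled Enrolled dyads.
#' @param retention Probability a dyad completes all sessions.
#' @param n_items Pool size (must match the codebook).
#' @param n_informative_items Number of items loading on the latent factor.
#' @param item_loading Standardized loading of informative items on the
#'   latent factor (correlation scale, in `[0, 1)`).
#' @param effect_beta Score-to-BMI-z slope on the standardized scale, in
#'   `[0, 1]`; 0 switches the anthropometric signal off.
#' @param biomarker_loadings Named signed correlations of each log-analyte
#'   with BMI z; `NULL` for the defaults below, or a single number to scale
#'   the default magnitudes.
#' @param bmi_z_center,bmi_z_sd Marginal location/scale of the realized BMI
#'   z-scores (defaults 0.6 and 1.1, a cohort skewed toward overweight).
#' @param whtr_center,whtr_sd,whtr_rho Waist-to-height marginal center/scale
#'   and its correlation with BMI z.
#' @param missing_anthro Probability a completer's anthropometry is missing.
#' @param incomplete_instrument Probability a completer skips one item.
#' @param blood_given Probability a completer donates blood.
#' @param short_sample_rate Probability a donor's sample is short, under
#'   which each analyte is missing with probability `missing_biomarker`
#'   (clustered missingness: per-analyte n and per-index complete-case n
#'   cannot both match the study under independent missingness).
#' @param missing_biomarker Conditional per-analyte missing probability for
#'   short samples.
#' @param plates Number of immunoassay plates.
#' @param plate_sd SD of the log-normal multiplicative plate effect.
#' @param replicate_cv Within-assay replicate coefficient of variation.
#' @param mar_attrition If `TRUE`, dropout depends on parent age and
#'   employment (for attrition-test power checks); default MCAR.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_enrolled = 273, retention = 206 / 273, n_items = 45,
                       n_informative_items = 18, item_loading = 0.3,
                       effect_beta = 0.5, biomarker_loadings = NULL,
                       bmi_z_center = 0.6, bmi_z_sd = 1.1,
                       whtr_center = 50.5, whtr_sd = 4, whtr_rho = 0.6,
                       missing_anthro = 6 / 206,
                       incomplete_instrument = 4 / 206,
                       blood_given = 190 / 206, short_sample_rate = 0.25,
                       missing_biomarker = 0.55, plates = 7, plate_sd = 0.08,
                       replicate_cv = 0.04, mar_attrition = FALSE) {
  stopifnot(n_enrolled >= 1, n_items >= 1,
            n_informative_items <= n_items, n_informative_items >= 1)
  fracs <- c(retention = retention, missing_anthro = missing_anthro,
             incomplete_instrument = incomplete_instrument,
             blood_given = blood_given, short_sample_rate = short_sample_rate,
             missing_biomarker = missing_biomarker)
  if (any(fracs < 0) || any(fracs > 1))
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (item_loading < 0 || item_loading >= 1) stop("item_loading must be in [0, 1)")
  if (effect_beta < 0 || effect_beta > 1) stop("effect_beta must be in [0, 1]")
  if (plates < 1) stop("need at least one plate")
  if (is.null(biomarker_loadings)) {
    biomarker_loadings <- default_biomarker_loadings()
  } else if (is.numeric(biomarker_loadings) && is.null(names(biomarker_loadings)) &&
             length(biomarker_loadings) == 1L) {
    biomarker_loadings <- default_biomarker_loadings() * biomarker_loadings /
      max(abs(default_biomarker_loadings()))
  }
  structure(list(n_enrolled = n_enrolled, retention = retention,
                 n_items = n_items, n_informative_items = n_informative_items,
                 item_loading = item_loading, effect_beta = effect_beta,
                 biomarker_loadings = biomarker_loadings,
                 bmi_z_center = bmi_z_center, bmi_z_sd = bmi_z_sd,
                 whtr_center = whtr_center, whtr_sd = whtr_sd,
                 whtr_rho = whtr_rho, missing_anthro = missing_anthro,
                 incomplete_instrument = incomplete_instrument,
                 blood_given = blood_given,
                 short_sample_rate = short_sample_rate,
                 missing_biomarker = missing_biomarker, plates = plates,
                 plate_sd = plate_sd, replicate_cv = replicate_cv,
                 mar_attrition = mar_attrition),
            class = "sim_config")
}

#' Default signed biomarker loadings on BMI z
#'
#' Signs follow the analytes' documented relationship to child BMI: risk
#' markers positive, HDL-C and the anti-inflammatory analytes (adiponectin,
#' IGFBP-1, IL-10) negative; total cholesterol carries a weaker positive
#' loading.
#' @return Named numeric vector (correlation scale).
#' @export
default_biomarker_loadings <- function() {
  c(glucose = 0.5, insulin = 0.5, leptin = 0.5, adiponectin = -0.5,
    triglycerides = 0.5, total_cholesterol = 0.3, hdl_c = -0.5,
    igfbp1 = -0.5, il10 = -0.5, crp = 0.5, resistin = 0.5)
}

# marginal scales: median (analyte units) and log-sd, mid-range of pediatric
# literature reference bands
biomarker_scales <- function() {
  list(center = c(glucose = 85, insulin = 5, leptin = 3, adiponectin = 10,
                  triglycerides = 60, total_cholesterol = 160, hdl_c = 50,
                  igfbp1 = 30, il10 = 0.5, crp = 0.5, resistin = 10),
       sdlog = c(glucose = 0.07, insulin = 0.5, leptin = 0.7,
                 adiponectin = 0.35, triglycerides = 0.35,
                 total_cholesterol = 0.12, hdl_c = 0.18, igfbp1 = 0.6,
                 il10 = 0.5, crp = 0.9, resistin = 0.4))
}

immunoassay_analytes <- function() {
  c("insulin", "leptin", "adiponectin", "igfbp1", "il10", "crp", "resistin")
}
chemistry_analytes <- function() {
  c("glucose", "triglycerides", "total_cholesterol", "hdl_c")
}

# ordered-categorical item model constants: global thresholds put the
# baseline category mass at roughly (2, 7, 28, 45, 18)% -> most responses in
# options 3 and 4; fixed per-item intercept pattern spreads item means the
# way a real pool's do (roughly 2.9-4.3)
item_thresholds <- function() stats::qnorm(c(0.02, 0.09, 0.37, 0.82))
item_intercepts <- function(n_items)
  rep(c(-0.2, 0.15, 0.45, 0.75, 1.1), length.out = n_items)

#' Generate a synthetic parent/child dyad cohort
#'
#' Draws a latent adiposity-related factor `U` per dyad; informative item
#' scores come from an ordered 5-level probit model whose propensity is
#' `a_i + loading * U` (noise items drop the `U` term), mapped to option
#' scores on the half-point grid. The standardized realized total over the
#' informative items is the "score signal"; the child's BMI z-score is
#' `bmi_z_center + bmi_z_sd * (-effect_beta * signal + noise)`, realized to
#' height/weight via the inverse LMS transform against the packaged
#' reference, with waist tracking a waist-to-height ratio around 50.
#' Biomarkers are log-normal with log-scale mean shifted by
#' `loading * (standardized BMI z)`; immunoassay analytes go through
#' multiplicative plate effects (shared with each plate's internal control)
#' and replicate noise at `replicate_cv` (triplicates; IGFBP-1 duplicates).
#' Dropout, anthropometry, instrument-completion and clustered biomarker
#' missingness are applied at the configured rates.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; a fixed seed reproduces the cohort exactly.
#' @param lms_ref LMS reference used to realize BMI (default packaged table).
#' @return List of class `cohort_bundle`: `responses`, `anthro`,
#'   `replicates`, `plate_controls`, `chemistry`, `demographics` (all
#'   completers; demographics also covers dropouts and carries `completing`),
#'   `truth` (latent factor, score signal, true BMI z per enrolled dyad —
#'   never consumed by the analysis modules), `codebook`,
#'   `instrument_items`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1,
                            lms_ref = load_lms_reference()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  n <- config$n_enrolled
  dyad_id <- sprintf("D%04d", seq_len(n))
  cb <- default_codebook()
  if (config$n_items != length(item_ids(cb)))
    stop("n_items must match the default codebook (", length(item_ids(cb)), ")")
  informative <- default_informative_items(cb, config$n_informative_items)

  U <- stats::rnorm(n)

  # --- item responses -------------------------------------------------------
  ids <- item_ids(cb)
  a <- item_intercepts(config$n_items)
  tau <- item_thresholds()
  lam <- config$item_loading
  scores <- matrix(NA_real_, n, config$n_items, dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    inf_j <- ids[j] %in% informative
    v <- a[j] + (if (inf_j) lam * U + sqrt(1 - lam^2) * stats::rnorm(n)
                 else stats::rnorm(n))
    cat_j <- findInterval(v, tau) + 1L
    scores[, j] <- unname(cb$items[[j]]$option_scores[cat_j])
  }
  total_true <- rowSums(scores[, informative, drop = FALSE])
  signal <- as.numeric(scale(total_true))

  # --- anthropometry --------------------------------------------------------
  beta <- config$effect_beta
  bmi_z <- config$bmi_z_center + config$bmi_z_sd *
    (-beta * signal + sqrt(max(0, 1 - beta^2)) * stats::rnorm(n))
  # keep z inside the Box-Cox support of the reference (extended z-scores
  # for extreme BMI are out of scope)
  bmi_z <- pmin(pmax(bmi_z, -4), 4)
  age <- stats::runif(n, 36, 72)
  sex <- sample(rep(c("female", "male"), length.out = n))
  lms <- lms_lookup(lms_ref, sex, age)
  bmi <- lms_inverse(bmi_z, lms$L, lms$M, lms$S)
  height <- 95 + 0.5 * (age - 36) + stats::rnorm(n, 0, 4)
  weight <- bmi * (height / 100)^2
  whtr <- config$whtr_center + config$whtr_sd *
    (config$whtr_rho * (bmi_z - config$bmi_z_center) / config$bmi_z_sd +
       sqrt(1 - config$whtr_rho^2) * stats::rnorm(n))
  waist <- whtr * height / 100

  # --- biomarker true values ------------------------------------------------
  sc <- biomarker_scales()
  loadings <- config$biomarker_loadings
  z_adip <- (bmi_z - config$bmi_z_center) / config$bmi_z_sd
  analytes <- names(sc$center)
  biom <- sapply(analytes, function(an) {
    l <- if (an %in% names(loadings)) loadings[[an]] else 0
    exp(log(sc$center[[an]]) + sc$sdlog[[an]] *
          (l * z_adip + sqrt(max(0, 1 - l^2)) * stats::rnorm(n)))
  })

  # --- retention and demographics ------------------------------------------
  parent_age <- stats::rnorm(n, 33.6, 6)
  employment <- sample(c("unemployed", "seasonal", "full_time"), n, TRUE,
                       prob = c(0.71, 0.17, 0.12))
  if (config$mar_attrition) {
    lp <- stats::qlogis(config$retention) + 0.35 * scale(parent_age)[, 1] +
      0.6 * (employment == "unemployed") - 0.4
    completing <- stats::runif(n) < stats::plogis(lp)
  } else {
    completing <- stats::runif(n) < config$retention
  }
  demographics <- data.frame(dyad_id = dyad_id, completing = completing,
                             parent_age = parent_age, employment = employment,
                             child_sex = sex, child_age_months = age,
                             stringsAsFactors = FALSE)

  comp <- which(completing)

  # --- responses table (completers; a few skip one item) --------------------
  responses <- data.frame(dyad_id = dyad_id[comp], stringsAsFactors = FALSE)
  resp_scores <- scores[comp, , drop = FALSE]
  skip <- stats::runif(length(comp)) < config$incomplete_instrument
  for (i in which(skip))
    resp_scores[i, sample(config$n_items, 1L)] <- NA_real_
  for (j in seq_along(ids)) responses[[ids[j]]] <- resp_scores[, j]

  # --- anthro table (two repeat measures, 0.1 precision) --------------------
  anthro_missing <- stats::runif(length(comp)) < config$missing_anthro
  mk_rep <- function(x, sd) round(x + stats::rnorm(length(x), 0, sd), 1)
  anthro <- data.frame(dyad_id = dyad_id[comp], sex = sex[comp],
                       age_months = age[comp],
                       height1_cm = mk_rep(height[comp], 0.3),
                       height2_cm = mk_rep(height[comp], 0.3),
                       weight_kg = round(weight[comp], 1),
                       waist1_cm = mk_rep(waist[comp], 0.5),
                       waist2_cm = mk_rep(waist[comp], 0.5),
                       stringsAsFactors = FALSE)
  anthro[anthro_missing, c("height1_cm", "height2_cm", "weight_kg",
                           "waist1_cm", "waist2_cm")] <- NA_real_

  # --- blood tables ---------------------------------------------------------
  donors <- comp[stats::runif(length(comp)) < config$blood_given]
  short <- stats::runif(length(donors)) < config$short_sample_rate
  present <- matrix(TRUE, length(donors), length(analytes),
                    dimnames = list(NULL, analytes))
  if (any(short)) {
    miss <- matrix(stats::runif(sum(short) * length(analytes)) <
                     config$missing_biomarker, sum(short))
    present[short, ] <- !miss
  }
  plate_of <- rep(sprintf("P%d", seq_len(config$plates)),
                  length.out = length(donors))
  plate_factor <- stats::setNames(
    exp(stats::rnorm(config$plates, 0, config$plate_sd)),
    sprintf("P%d", seq_len(config$plates)))

  rep_rows <- list()
  for (an in immunoassay_analytes()) {
    keep <- which(present[, an])
    if (!length(keep)) next
    k <- if (an == "igfbp1") 2L else 3L
    m <- biom[donors[keep], an] * plate_factor[plate_of[keep]]
    reps <- matrix(m, length(keep), 3) *
      exp(matrix(stats::rnorm(length(keep) * 3, 0, config$replicate_cv),
                 length(keep), 3))
    if (k == 2L) reps[, 3] <- NA_real_
    rep_rows[[an]] <- data.frame(dyad_id = dyad_id[donors[keep]], analyte = an,
                                 plate_id = plate_of[keep],
                                 rep1 = reps[, 1], rep2 = reps[, 2],
                                 rep3 = reps[, 3], stringsAsFactors = FALSE)
  }
  replicates <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(dyad_id = character(), analyte = character(),
               plate_id = character(), rep1 = numeric(), rep2 = numeric(),
               rep3 = numeric(), stringsAsFactors = FALSE)
  rownames(replicates) <- NULL

  plate_controls <- do.call(rbind, lapply(immunoassay_analytes(), function(an) {
    data.frame(analyte = an, plate_id = names(plate_factor),
               value = sc$center[[an]] * unname(plate_factor),
               stringsAsFactors = FALSE)
  }))

  chem <- data.frame(dyad_id = dyad_id[donors], stringsAsFactors = FALSE)
  for (an in chemistry_analytes()) {
    v <- biom[donors, an] * exp(stats::rnorm(length(donors), 0, 0.02))
    v[!present[, an]] <- NA_real_
    chem[[an]] <- v
  }

  truth <- data.frame(dyad_id = dyad_id, U = U, score_signal = signal,
                      total_true = total_true, bmi_z_true = bmi_z,
                      completing = completing, stringsAsFactors = FALSE)

  structure(list(responses = responses, anthro = anthro,
                 replicates = replicates, plate_controls = plate_controls,
                 chemistry = chem, demographics = demographics, truth = truth,
                 codebook = cb, instrument_items = informative,
                 config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("synthetic dyad cohort: ", nrow(x$truth), " enrolled, ",
      nrow(x$responses), " completing; ", length(x$instrument_items),
      " instrument items\n", sep = "")
  invisible(x)
}

#' Realized cohort shape against the study's stated bands
#'
#' Generates one cohort (or several, averaging) and reports realized counts
#' next to the expected study shape: about 206 completing dyads, about 200
#' with anthropometry, about 190 blood donors and roughly 159-163
#' observations per biomarker.
#'
#' @param config A [sim_config()].
#' @param seed Base seed.
#' @param n_seeds Number of cohorts to average over (default 1).
#' @return Data frame with `quantity`, `realized` (mean over seeds),
#'   `expected_low`, `expected_high`.
#' @export
emulate_study_shape <- function(config = sim_config(), seed = 1, n_seeds = 1) {
  one <- function(s) {
    ch <- simulate_cohort(config, seed = s)
    analyte_n <- c(
      vapply(immunoassay_analytes(),
             function(an) sum(ch$replicates$analyte == an), numeric(1)),
      vapply(chemistry_analytes(),
             function(an) sum(!is.na(ch$chemistry[[an]])), numeric(1)))
    c(enrolled = nrow(ch$truth),
      completing = nrow(ch$responses),
      instrument_complete = sum(stats::complete.cases(
        ch$responses[, item_ids(ch$codebook)])),
      anthro_measured = sum(!is.na(ch$anthro$weight_kg)),
      blood_donors = nrow(ch$chemistry),
      biomarker_n_median = stats::median(analyte_n))
  }
  realized <- rowMeans(vapply(seq_len(n_seeds) - 1L + seed, one, numeric(6)))
  exp_n <- config$n_enrolled * config$retention
  bands <- rbind(
    enrolled = c(config$n_enrolled, config$n_enrolled),
    completing = exp_n + c(-3, 3) * sqrt(exp_n * (1 - config$retention)),
    instrument_complete = exp_n * (1 - config$incomplete_instrument) + c(-8, 8),
    anthro_measured = exp_n * (1 - config$missing_anthro) + c(-8, 8),
    blood_donors = exp_n * config$blood_given + c(-10, 10),
    biomarker_n_median = exp_n * config$blood_given *
      (1 - config$short_sample_rate * config$missing_biomarker) + c(-12, 12))
  data.frame(quantity = names(realized), realized = unname(realized),
             expected_low = bands[, 1], expected_high = bands[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-call study twin: simulate then validate
#'
#' Convenience wrapper: generates a cohort and runs the full validation
#' pipeline on its fixed instrument items.
#'
#' @inheritParams simulate_cohort
#' @inheritParams run_validation
#' @param ... Passed to [run_validation()].
#' @return As [run_validation()], plus the `cohort`.
#' @export
run_study <- function(config = sim_config(), seed = 1, threshold = 75,
                      scaling = NULL, ...) {
  cohort <- simulate_cohort(config, seed = seed)
  res <- run_validation(cohort, cohort$codebook, cohort$instrument_items,
                        threshold = threshold, scaling = scaling, ...)
  res$cohort <- cohort
  res
}
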