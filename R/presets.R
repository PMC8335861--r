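# Named coefficient presets bundling published growth-curve estimates so
# simulations can use them as ground truth in parameter-recovery studies.
# Terms are named by design-matrix column; `:` denotes a product term.

preset_registry <- function() {
  m1 <- c(
    "(Intercept)" = 1.55, "age_c" = 0.49, "age_c2" = -0.005,
    "age_c:cohort" = -0.143, "age_c2:cohort" = -0.001,
    "cohort" = -0.232, "hukou_urban" = -0.228,
    "edu_illiterate" = -0.088, "edu_elementary" = 0.031,
    "log_income" = -0.014, "female" = -0.011, "no_spouse" = 0.13,
    "died_or_lost" = -0.108, "hosp_oop_pct" = 0.00002,
    "visit_oop_pct" = 0.007, "hosp_oop_q2" = -0.116,
    "hosp_total_q2" = -0.038, "visit_oop_q2" = -0.276,
    "visit_total_q2" = 0.042, "smoking" = -0.045, "drinking" = 0.002
  )
  m2 <- c(
    "(Intercept)" = 2.449, "age_c" = 0.575, "age_c2" = -0.004,
    "age_c:cohort" = -0.138, "age_c2:cohort" = -0.002,
    "age_c:edu_illiterate" = 0.035, "age_c:edu_elementary" = 0.028,
    "age_c:hukou_urban" = -0.037, "age_c:log_income" = -0.021,
    "age_c2:edu_illiterate" = 0.001, "age_c2:edu_elementary" = 0.0002,
    "age_c2:hukou_urban" = 0.000236, "age_c2:log_income" = -0.001,
    "cohort" = -0.301, "hukou_urban" = -0.666,
    "edu_illiterate" = 0.299, "edu_elementary" = 0.342,
    "log_income" = -0.235, "female" = -0.007, "no_spouse" = 0.128,
    "died_or_lost" = -0.1, "hosp_oop_pct" = 0.00002,
    "visit_oop_pct" = 0.007, "hosp_oop_q2" = -0.118,
    "hosp_total_q2" = -0.033, "visit_oop_q2" = -0.276,
    "visit_total_q2" = 0.042, "smoking" = -0.046, "drinking" = 0.001
  )
  m3 <- c(
    "(Intercept)" = 1.882, "age_c" = 0.982, "age_c2" = -0.013,
    "age_c:cohort" = -0.315, "age_c2:cohort" = -0.003,
    "age_c:edu_illiterate" = 0.128, "age_c:edu_elementary" = 0.11,
    "age_c:hukou_urban" = -0.135, "age_c:log_income" = -0.108,
    "age_c:cohort:edu_illiterate" = -0.041,
    "age_c:cohort:edu_elementary" = -0.034,
    "age_c:cohort:hukou_urban" = 0.039, "age_c:cohort:log_income" = 0.039,
    "age_c2:edu_illiterate" = -0.001, "age_c2:edu_elementary" = -0.002,
    "age_c2:hukou_urban" = 0.004, "age_c2:log_income" = 0.001,
    "age_c2:cohort:edu_illiterate" = -0.001,
    "age_c2:cohort:edu_elementary" = -0.00008,
    "age_c2:cohort:hukou_urban" = -0.0003,
    "age_c2:cohort:log_income" = 0.001,
    "cohort" = -0.321, "hukou_urban" = -0.541,
    "edu_illiterate" = 0.155, "edu_elementary" = 0.216,
    "log_income" = -0.117, "female" = 0.000423, "no_spouse" = 0.127,
    "died_or_lost" = -0.083, "hosp_oop_pct" = 0.00003,
    "visit_oop_pct" = 0.007, "hosp_oop_q2" = -0.14,
    "hosp_total_q2" = -0.01, "visit_oop_q2" = -0.271,
    "visit_total_q2" = 0.032, "smoking" = -0.05, "drinking" = 0.002
  )
  male <- c(
    "(Intercept)" = 1.048, "age_c" = 0.978, "age_c2" = -0.015,
    "age_c:cohort" = -0.317, "age_c2:cohort" = -0.003,
    "age_c:edu_illiterate" = 0.09, "age_c:edu_elementary" = 0.086,
    "age_c:hukou_urban" = -0.064, "age_c:log_income" = -0.116,
    "age_c:cohort:edu_illiterate" = -0.026,
    "age_c:cohort:edu_elementary" = -0.024,
    "age_c:cohort:hukou_urban" = 0.014, "age_c:cohort:log_income" = 0.042,
    "age_c2:edu_illiterate" = 0.001, "age_c2:edu_elementary" = -0.001,
    "age_c2:hukou_urban" = 0.002, "age_c2:log_income" = 0.002,
    "age_c2:cohort:edu_illiterate" = -0.001,
    "age_c2:cohort:edu_elementary" = -0.00021,
    "age_c2:cohort:hukou_urban" = -0.00008,
    "age_c2:cohort:log_income" = 0.000364,
    "cohort" = -0.343, "hukou_urban" = -0.496,
    "edu_illiterate" = 0.183, "edu_elementary" = 0.204,
    "log_income" = -0.113, "no_spouse" = 0.207,
    "died_or_lost" = -0.093, "hosp_oop_pct" = -0.00009,
    "visit_oop_pct" = 0.007, "hosp_oop_q2" = 0.288,
    "hosp_total_q2" = -0.133, "visit_oop_q2" = 0.129,
    "visit_total_q2" = 0.099, "smoking" = 0.261, "drinking" = 0.01
  )
  female <- c(
    "(Intercept)" = 2.137, "age_c" = 1.03, "age_c2" = -0.01,
    "age_c:cohort" = -0.325, "age_c2:cohort" = -0.004,
    "age_c:edu_illiterate" = 0.153, "age_c:edu_elementary" = 0.127,
    "age_c:hukou_urban" = -0.24, "age_c:log_income" = -0.1,
    "age_c:cohort:edu_illiterate" = -0.054,
    "age_c:cohort:edu_elementary" = -0.042,
    "age_c:cohort:hukou_urban" = 0.075, "age_c:cohort:log_income" = 0.035,
    "age_c2:edu_illiterate" = -0.003, "age_c2:edu_elementary" = -0.003,
    "age_c2:hukou_urban" = 0.007, "age_c2:log_income" = -0.00023,
    "age_c2:cohort:edu_illiterate" = 0.000031,
    "age_c2:cohort:edu_elementary" = 0.000026,
    "age_c2:cohort:hukou_urban" = -0.001,
    "age_c2:cohort:log_income" = 0.001,
    "cohort" = -0.278, "hukou_urban" = -0.632,
    "edu_illiterate" = -0.088, "edu_elementary" = 0.216,
    "log_income" = -0.133, "no_spouse" = -0.042,
    "died_or_lost" = -0.051, "hosp_oop_pct" = 0.001,
    "visit_oop_pct" = 0.114, "hosp_oop_q2" = -0.178,
    "hosp_total_q2" = 0.308, "visit_oop_q2" = 0.452,
    "visit_total_q2" = -0.293, "smoking" = -0.209, "drinking" = 0.04
  )
  list(
    model1 = list(fixed = m1,
                  random = c(var_intercept = 10.34, cov = 0.498,
                             var_slope = 0.035, residual = 0.209),
                  slope_moderators = "cohort", curvature_moderators = "cohort",
                  stratum = "all"),
    model2 = list(fixed = m2,
                  random = c(var_intercept = 10.314, cov = 0.496,
                             var_slope = 0.035, residual = 0.209),
                  slope_moderators = c("cohort", "ses"),
                  curvature_moderators = c("cohort", "ses"),
                  stratum = "all"),
    model3 = list(fixed = m3,
                  random = c(var_intercept = 10.291, cov = 0.496,
                             var_slope = 0.035, residual = 0.207),
                  slope_moderators = c("cohort", "ses", "cohort_x_ses"),
                  curvature_moderators = c("cohort", "ses", "cohort_x_ses"),
                  stratum = "all"),
    male = list(fixed = male,
                random = c(var_intercept = 10.634, cov = 0.521,
                           var_slope = 0.036, residual = 0.214),
                slope_moderators = c("cohort", "ses", "cohort_x_ses"),
                curvature_moderators = c("cohort", "ses", "cohort_x_ses"),
                stratum = "male"),
    female = list(fixed = female,
                  random = c(var_intercept = 9.675, cov = 0.448,
                             var_slope = 0.034, residual = 0.192),
                  slope_moderators = c("cohort", "ses", "cohort_x_ses"),
                  curvature_moderators = c("cohort", "ses", "cohort_x_ses"),
                  stratum = "female")
  )
}

#' Published coefficient presets for simulation truth
#'
#' Returns a named preset bundling a full fixed-effect vector, the
#' random-effect (co)variances and residual variance, and the matching model
#' structure. Presets `"model1"` (cohort moderation only), `"model2"` (adds
#' SES moderation of the age and age-squared slopes), `"model3"` (adds
#' cohort-by-SES cross-level interactions), and the gender-stratified
#' `"male"`/`"female"` sets are available. They serve as ground truth in
#' parameter-recovery simulations.
#'
#' @param name preset name.
#' @return list with elements `fixed` (named coefficients), `random`
#'   (`var_intercept`, `cov`, `var_slope`, `residual`), moderator menus and
#'   the stratum the preset describes.
#' @export
model_preset <- function(name = c("model1", "model2", "model3", "male", "female")) {
  name <- match.arg(name)
  preset_registry()[[name]]
}

#' Truth configuration for the synthetic panel generator
#'
#' Bundles every parameter the generator needs: cohort and SES mixes,
#' disease-onset hazards, attrition, the growth-model truth (fixed effects,
#' random-effect covariance, residual variance) and the seed. Defaults
#' emulate a CHARLS-like four-wave survey of roughly 15,000 adults born
#' 1942-1964: cohort shares 0.152/0.300/0.281/0.267, about 80% rural,
#' three-level education with younger cohorts more educated, per-cohort
#' log10 income means rising from 4.17 to 4.54, and per-wave death/loss
#' probabilities of about 2% each.
#'
#' @param n_individuals number of persons at baseline.
#' @param wave_years calendar years of the survey waves.
#' @param preset optional preset name passed to [model_preset()]; fills
#'   `fixed_effects` and `random` unless overridden.
#' @param fixed_effects named coefficient vector (simulation truth).
#' @param random_cov 2x2 (or 3x3) random-effect covariance matrix.
#' @param residual_var level-1 residual variance.
#' @param cohort_mix length-4 proportions over the birth cohorts.
#' @param ses_mix list with `urban_frac`, `edu_probs` (4x3 matrix),
#'   `log_income_mean`, `log_income_sd`, `female_frac`, `no_spouse_frac`,
#'   `smoking_frac`, `drinking_frac`, each per cohort.
#' @param disease_params data frame of per-disease onset hazards
#'   (`disease`, `base_hazard` annual probability at age 60, `age_slope`
#'   on the logit per year of age).
#' @param attrition list with per-wave `death_prob`, `loss_prob`,
#'   `outcome_coef` (logit shift in the death probability per DALY unit of
#'   the current, then-unobserved outcome; 0 = noninformative dropout), and
#'   optionally `died_effect` (terminal-decline elevation, in DALY years,
#'   of the observed trajectory of persons who die; makes the death
#'   indicator a genuine component of the outcome process) and
#'   `selection_on` (`"outcome"`, the realized current outcome, or
#'   `"expected"`, its fixed-effect systematic part).
#' @param truncate_outcome if `TRUE`, model-based outcomes are floored at 0
#'   (off by default: the growth model is an unconstrained Gaussian model).
#' @param seed integer RNG seed.
#' @return a validated `truth_config` list.
#' @export
truth_config <- function(n_individuals = 15000,
                         wave_years = c(2011, 2013, 2015, 2018),
                         preset = "model1",
                         fixed_effects = NULL,
                         random_cov = NULL,
                         residual_var = NULL,
                         cohort_mix = c(0.152, 0.300, 0.281, 0.267),
                         ses_mix = default_ses_mix(),
                         disease_params = default_disease_params(),
                         attrition = list(death_prob = 0.02, loss_prob = 0.02,
                                          outcome_coef = 0),
                         truncate_outcome = FALSE,
                         seed = 1L) {
  if (!is.null(preset)) {
    pr <- model_preset(preset)
    if (is.null(fixed_effects)) fixed_effects <- pr$fixed
    if (is.null(random_cov))
      random_cov <- matrix(c(pr$random["var_intercept"], pr$random["cov"],
                             pr$random["cov"], pr$random["var_slope"]),
                           2, 2, dimnames = list(c("u0", "u1"), c("u0", "u1")))
    if (is.null(residual_var)) residual_var <- unname(pr$random["residual"])
  }
  cfg <- list(n_individuals = n_individuals, wave_years = sort(wave_years),
              preset = preset, fixed_effects = fixed_effects,
              random_cov = random_cov, residual_var = residual_var,
              cohort_mix = cohort_mix, ses_mix = ses_mix,
              disease_params = disease_params, attrition = attrition,
              truncate_outcome = truncate_outcome, seed = as.integer(seed))
  class(cfg) <- "truth_config"
  validate_truth_config(cfg)
  cfg
}

validate_truth_config <- function(cfg) {
  with(cfg, {
    if (n_individuals < 0 || n_individuals != round(n_individuals))
      stop("configuration error in field 'n_individuals': must be a nonnegative count")
    if (length(wave_years) < 1) stop("configuration error in field 'wave_years'")
    if (abs(sum(cohort_mix) - 1) > 1e-8 || any(cohort_mix < 0))
      stop("configuration error in field 'cohort_mix': must be proportions summing to 1")
    if (any(abs(rowSums(ses_mix$edu_probs) - 1) > 1e-8))
      stop("configuration error in field 'ses_mix$edu_probs': rows must sum to 1")
    if (!is.null(random_cov)) {
      if (!isSymmetric(unname(random_cov)))
        stop("configuration error in field 'random_cov': must be symmetric")
      ev <- eigen(random_cov, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8)
        stop("configuration error in field 'random_cov': must be positive semi-definite")
    }
    if (!is.null(residual_var) && residual_var < 0)
      stop("configuration error in field 'residual_var': must be >= 0")
    pw <- attrition$death_prob + attrition$loss_prob
    if (any(pw < 0) || any(pw > 1))
      stop("configuration error in field 'attrition': death+loss probability outside [0, 1]")
    if (any(disease_params$base_hazard < 0 | disease_params$base_hazard > 1))
      stop("configuration error in field 'disease_params': hazards outside [0, 1]")
  })
  invisible(cfg)
}

#' @rdname truth_config
#' @export
default_ses_mix <- function() {
  list(
    urban_frac = c(0.224, 0.203, 0.184, 0.182),
    edu_probs = matrix(c(0.303, 0.465, 0.232,
                         0.294, 0.498, 0.208,
                         0.249, 0.371, 0.380,
                         0.125, 0.316, 0.559),
                       nrow = 4, byrow = TRUE,
                       dimnames = list(paste0("cohort", 1:4),
                                       c("illiterate", "elementary", "middle_or_higher"))),
    log_income_mean = c(4.17, 4.29, 4.41, 4.54),
    log_income_sd = c(0.61, 0.59, 0.59, 0.52),
    female_frac = c(0.467, 0.506, 0.504, 0.540),
    no_spouse_frac = c(0.200, 0.163, 0.150, 0.145),
    smoking_frac = c(0.424, 0.410, 0.413, 0.354),
    drinking_frac = c(0.303, 0.244, 0.245, 0.228)
  )
}

#' @rdname truth_config
#' @export
default_disease_params <- function() {
  data.frame(
    disease = c("hypertension", "diabetes", "cancer", "chronic_lung_disease",
                "hepatic_disease", "heart_disease", "stroke", "kidney_disease",
                "gastric_disease", "emotional_mental", "memory_disease",
                "arthritis_rheumatism", "asthma"),
    base_hazard = c(0.020, 0.008, 0.002, 0.006, 0.003, 0.010, 0.004,
                    0.005, 0.012, 0.006, 0.003, 0.020, 0.004),
    age_slope = c(0.04, 0.04, 0.05, 0.04, 0.01, 0.05, 0.06,
                  0.03, 0.01, 0.00, 0.08, 0.03, 0.01),
    stringsAsFactors = FALSE
  )
}
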