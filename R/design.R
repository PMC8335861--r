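ses_columns <- function() c("edu_illiterate", "edu_elementary", "hukou_urban", "log_income")

default_intercept_covariates <- function(include_female = TRUE) {
  c("cohort", "hukou_urban", "edu_illiterate", "edu_elementary", "log_income",
    if (include_female) "female",
    "no_spouse", "died_or_lost", "hosp_oop_pct", "visit_oop_pct",
    "hosp_oop_q2", "hosp_total_q2", "visit_oop_q2", "visit_total_q2",
    "smoking", "drinking")
}

#' Growth-curve model specification
#'
#' Declares which terms enter the two-level quadratic growth model. The
#' level-1 trajectory is quadratic in cohort-median-centered age; level-2
#' equations let cohort, SES (education contrasts, urban residence, log
#' income) and cohort-by-SES products moderate the intercept, the age slope
#' and the age-squared curvature. Moderator menus accept the shorthand
#' `"cohort"`, `"ses"`, `"cohort_x_ses"` or explicit column names.
#'
#' @param outcome name of the outcome column (DALYs).
#' @param slope_moderators terms moderating the linear age slope.
#' @param curvature_moderators terms moderating the age-squared slope.
#' @param intercept_covariates level-2 covariates of the intercept/outcome
#'   model (cohort, SES main effects, demographic, expenditure, behaviour
#'   and attrition controls).
#' @param random_structure `"intercept_slope"` (random intercept + linear
#'   age slope, the default) or `"intercept_slope_curvature"`.
#' @param estimation `"ML"` (default; required for -2LL/AIC/BIC comparison
#'   across fixed-effect sets) or `"REML"`.
#' @param quadratic if `FALSE`, drop the age-squared term and all curvature
#'   moderators, giving the simple linear growth model (used for curve-shape
#'   comparison by -2LL/AIC/BIC).
#' @return a `growth_spec` object.
#' @export
growth_spec <- function(outcome = "dalys",
                        slope_moderators = "cohort",
                        curvature_moderators = "cohort",
                        intercept_covariates = default_intercept_covariates(),
                        random_structure = c("intercept_slope",
                                             "intercept_slope_curvature"),
                        estimation = c("ML", "REML"),
                        quadratic = TRUE) {
  spec <- list(outcome = outcome, quadratic = quadratic,
               slope_moderators = slope_moderators,
               curvature_moderators = if (quadratic) curvature_moderators
                                      else character(0),
               intercept_covariates = intercept_covariates,
               random_structure = match.arg(random_structure),
               estimation = match.arg(estimation))
  class(spec) <- "growth_spec"
  spec
}

#' @rdname growth_spec
#' @param preset preset name, see [model_preset()].
#' @param include_female keep the gender main effect (dropped in
#'   gender-stratified runs).
#' @export
spec_from_preset <- function(preset, include_female = NULL) {
  pr <- model_preset(preset)
  if (is.null(include_female)) include_female <- pr$stratum == "all"
  growth_spec(slope_moderators = pr$slope_moderators,
              curvature_moderators = pr$curvature_moderators,
              intercept_covariates = default_intercept_covariates(include_female))
}

expand_moderators <- function(mods) {
  out <- character(0)
  for (m in mods) {
    out <- c(out, switch(m,
      cohort = "cohort",
      ses = ses_columns(),
      cohort_x_ses = paste0("cohort:", ses_columns()),
      m))
  }
  unique(out)
}

#' Build design matrices for the growth model
#'
#' Expands a coded panel and a [growth_spec()] into the response vector, the
#' named fixed-effects matrix (intercept, centered age and its square, all
#' age-by-moderator and age-squared-by-moderator product columns, and the
#' intercept covariates) and the per-observation random-effects matrix
#' (`[1, age_c]`, optionally with `age_c2`). Rows are sorted by person and
#' wave so each person's observations are contiguous.
#'
#' @param coded a `coded_panel`.
#' @param spec a `growth_spec`.
#' @param outcome_required if `FALSE`, a missing outcome column yields
#'   `y = NULL` instead of an error (used when simulating the outcome).
#' @return list with `y`, `X`, `Z`, `data` (the sorted panel), `persons`,
#'   `person_index` (row to person), `grp_start`/`grp_len` (0-based
#'   contiguous person blocks).
#' @export
build_design <- function(coded, spec, outcome_required = TRUE) {
  stopifnot(inherits(spec, "growth_spec"))
  ord <- order(coded$person_id, coded$wave_year)
  d <- coded[ord, , drop = FALSE]

  slope <- expand_moderators(spec$slope_moderators)
  curv <- expand_moderators(spec$curvature_moderators)
  needed <- unique(c("age_c", "age_c2",
                     unlist(strsplit(c(slope, curv), ":", fixed = TRUE)),
                     spec$intercept_covariates))
  miss <- setdiff(needed, names(d))
  if (length(miss))
    stop("coded panel missing column(s) required by the model spec: ",
         paste(miss, collapse = ", "))

  prod_col <- function(base, term) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    v <- d[[base]]
    for (p in parts) v <- v * d[[p]]
    v
  }
  cols <- list("(Intercept)" = rep(1, nrow(d)), age_c = d$age_c)
  if (isTRUE(spec$quadratic) || is.null(spec$quadratic)) cols$age_c2 <- d$age_c2
  for (m in slope) cols[[paste0("age_c:", m)]] <- prod_col("age_c", m)
  if (!is.null(cols$age_c2))
    for (m in curv) cols[[paste0("age_c2:", m)]] <- prod_col("age_c2", m)
  for (v in spec$intercept_covariates) cols[[v]] <- d[[v]]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("fixed-effects matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  Z <- if (spec$random_structure == "intercept_slope") {
    cbind(1, d$age_c)
  } else {
    cbind(1, d$age_c, d$age_c2)
  }
  colnames(Z) <- c("u0", "u1", if (ncol(Z) == 3) "u2")

  persons <- unique(d$person_id)
  person_index <- match(d$person_id, persons)
  grp_len <- tabulate(person_index, nbins = length(persons))
  grp_start <- c(0L, cumsum(grp_len)[-length(grp_len)])

  y <- if (spec$outcome %in% names(d)) as.numeric(d[[spec$outcome]])
       else if (outcome_required) stop("outcome column '", spec$outcome, "' not found")
       else NULL
  if (!is.null(y) && anyNA(y)) stop("outcome contains missing values")

  list(y = y, X = X, Z = Z, data = d, persons = persons,
       person_index = person_index,
       grp_start = as.integer(grp_start), grp_len = as.integer(grp_len),
       spec = spec)
}
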