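evaluate_term <- function(term, age_c, profile) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  v <- rep(1, length(age_c))
  for (p in parts) {
    v <- v * switch(p,
      "(Intercept)" = 1,
      "age_c" = age_c,
      "age_c2" = age_c^2,
      {
        if (!p %in% names(profile))
          stop("covariate profile missing term '", p, "'")
        profile[[p]]
      })
  }
  v
}

#' Predicted DALY trajectories over age
#'
#' Evaluates the fitted fixed-effect mean at each (profile, age) pair — an
#' exact quadratic in centered age, no smoothing — and back-transforms
#' centered age to actual age using the per-cohort centering medians so
#' each cohort occupies its observed age window. Controls are held at the
#' values given in the profile (typically reference categories for dummies
#' and sample means for continuous controls). Optional pointwise Wald bands
#' use the fixed-effect covariance.
#'
#' @param fit a `growth_fit`.
#' @param profiles data frame, one row per group, containing every
#'   non-age covariate the fit uses plus optional `label` and `cohort`
#'   columns.
#' @param age_c_grid numeric vector of centered ages, or a named list per
#'   profile row; defaults to `seq(-8, 8, by = 0.5)`.
#' @param cohort_medians named vector mapping cohort code to centering
#'   median (from the codebook); when supplied, an `age` column with actual
#'   age is added.
#' @param level confidence level for the Wald band (`NULL` to skip).
#' @return a `trajectory_grid` data frame: `label`, `age_c`, `age`
#'   (if medians supplied), `pred`, `lo`, `hi`.
#' @export
predict_trajectories <- function(fit, profiles, age_c_grid = seq(-8, 8, 0.5),
                                 cohort_medians = NULL, level = 0.95) {
  stopifnot(inherits(fit, "growth_fit"), is.data.frame(profiles))
  beta <- stats::setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  if (is.null(profiles$label))
    profiles$label <- paste0("profile", seq_len(nrow(profiles)))
  out <- list()
  for (r in seq_len(nrow(profiles))) {
    prof <- as.list(profiles[r, , drop = FALSE])
    grid <- if (is.list(age_c_grid)) age_c_grid[[r]] else age_c_grid
    Xg <- vapply(names(beta), function(tm) evaluate_term(tm, grid, prof),
                 numeric(length(grid)))
    Xg <- matrix(Xg, nrow = length(grid),
                 dimnames = list(NULL, names(beta)))
    pred <- as.numeric(Xg %*% beta)
    lo <- hi <- rep(NA_real_, length(grid))
    if (!is.null(level)) {
      sepred <- sqrt(rowSums((Xg %*% fit$vcov_fixed) * Xg))
      zq <- qnorm(1 - (1 - level) / 2)
      lo <- pred - zq * sepred
      hi <- pred + zq * sepred
    }
    df <- data.frame(label = prof$label, age_c = grid, pred = pred,
                     lo = lo, hi = hi, stringsAsFactors = FALSE)
    if (!is.null(cohort_medians) && !is.null(prof$cohort))
      df$age <- grid + cohort_medians[[as.character(prof$cohort)]]
    out[[r]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "basis") <- list(estimation = fit$estimation,
                             profile_policy = "as supplied",
                             level = level)
  class(res) <- c("trajectory_grid", "data.frame")
  res
}

#' Gender-stratified growth-model fit
#'
#' Refits the growth model on one gender stratum with the gender main
#' effect removed from the covariates; all other machinery is identical to
#' [fit_growth()].
#'
#' @param coded a `coded_panel` containing a `female` indicator.
#' @param spec a [growth_spec()] for the pooled model.
#' @param stratum `"male"` or `"female"`.
#' @param ... passed to [fit_growth()].
#' @return a `growth_fit`.
#' @export
stratified_fit <- function(coded, spec, stratum = c("male", "female"), ...) {
  stratum <- match.arg(stratum)
  want <- if (stratum == "female") 1L else 0L
  sub <- coded[coded$female == want, , drop = FALSE]
  if (nrow(sub) == 0) stop("empty stratum: ", stratum)
  spec$intercept_covariates <- setdiff(spec$intercept_covariates, "female")
  fit_growth(sub, spec, ...)
}

#' Per-cohort descriptive table
#'
#' Summarizes a scored, coded panel in the customary descriptive layout:
#' mean (SD) of DALYs at each wave, N (%) for the categorical variables,
#' and mean (SD) of log income — per cohort and overall. Proportions for a
#' categorical variable are over that cohort's persons at baseline; DALY
#' rows are over observed person-waves. SD is reported as `NA` where a cell
#' has fewer than two observations.
#'
#' @param coded a `coded_panel` with a `dalys` column.
#' @return data frame with columns `section`, `item`, `cohort` (1-4 or
#'   `"all"`), `n`, `pct`, `mean`, `sd`.
#' @export
descriptive_table <- function(coded) {
  stopifnot("dalys" %in% names(coded))
  groups <- c(as.character(1:4), "all")
  rows <- list()
  add <- function(section, item, cohort, n = NA, pct = NA, mean = NA, sd = NA)
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, item = item, cohort = cohort, n = n, pct = pct,
      mean = mean, sd = sd, stringsAsFactors = FALSE)

  for (g in groups) {
    dd <- if (g == "all") coded else coded[coded$cohort == as.integer(g), ]
    for (w in sort(unique(coded$wave_year))) {
      x <- dd$dalys[dd$wave_year == w]
      add("disease_burden", paste0("dalys_", w), g,
          n = length(x),
          mean = if (length(x)) mean(x) else NA,
          sd = if (length(x) >= 2) sd(x) else NA)
    }
    # person-level categoricals at baseline
    base <- dd[!duplicated(dd$person_id), , drop = FALSE]
    np <- nrow(base)
    catvars <- list(
      female = c(male = 0, female = 1),
      hukou_urban = c(rural = 0, urban = 1),
      no_spouse = c(spouse = 0, no_spouse = 1),
      smoking = c(not_smoking = 0, smoking = 1),
      drinking = c(not_drinking = 0, drinking = 1)
    )
    if ("died_or_lost" %in% names(base))
      catvars$died_or_lost <- c(observed = 0, died_or_lost = 1)
    for (v in names(catvars)) {
      for (lab in names(catvars[[v]])) {
        cnt <- sum(base[[v]] == catvars[[v]][lab], na.rm = TRUE)
        add(v, lab, g, n = cnt, pct = if (np) 100 * cnt / np else NA)
      }
    }
    edu <- c(illiterate = "edu_illiterate", elementary = "edu_elementary")
    n_ill <- sum(base$edu_illiterate == 1, na.rm = TRUE)
    n_ele <- sum(base$edu_elementary == 1, na.rm = TRUE)
    n_mid <- np - n_ill - n_ele
    for (z in list(c("illiterate", n_ill), c("elementary", n_ele),
                   c("middle_or_higher", n_mid))) {
      add("education", z[1], g, n = as.numeric(z[2]),
          pct = if (np) 100 * as.numeric(z[2]) / np else NA)
    }
    x <- base$log_income
    add("income", "log_income", g, n = sum(!is.na(x)),
        mean = mean(x, na.rm = TRUE),
        sd = if (sum(!is.na(x)) >= 2) sd(x, na.rm = TRUE) else NA)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
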