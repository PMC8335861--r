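#' Generate a synthetic CHARLS-like longitudinal panel
#'
#' Draws a four-wave (by default) long-format panel of middle-aged and older
#' adults born 1942-1964: cohort membership, birth year, gender, urban/rural
#' residence, education, per-capita household income, marital status, health
#' behaviours, medical-expenditure amounts and out-of-pocket ratios, annual
#' Bernoulli disease-onset processes for the 13 chronic diseases (onsets are
#' absorbing: once diagnosed, always diagnosed), and between-wave death and
#' loss-to-follow-up. Onset histories start at age 45 so baseline
#' prevalence exists at the first wave.
#'
#' @param config a [truth_config()].
#' @return a `panel_dataset` data frame, one row per observed person-wave,
#'   with `onset_<disease>` columns carrying the onset year once the wave is
#'   at or after onset (`NA` before), `vital` (`observed`, or `died`/`lost`
#'   on the final record of an exiting person), and per-person `exit_status`
#'   / `exit_wave` columns.
#' @export
generate_panel <- function(config) {
  validate_truth_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  waves <- config$wave_years
  K <- length(waves)

  empty <- data.frame(person_id = character(0), wave_year = numeric(0),
                      birth_year = numeric(0), age = numeric(0))
  if (n == 0) {
    class(empty) <- c("panel_dataset", "data.frame")
    return(empty)
  }

  breaks <- cohort_breaks()
  cohort <- sample.int(4, n, replace = TRUE, prob = config$cohort_mix)
  lo <- breaks[1:4][cohort]
  hi <- (c(breaks[2:4] - 1L, breaks[5]))[cohort]
  birth_year <- lo + floor(runif(n) * (hi - lo + 1))

  sm <- config$ses_mix
  female <- rbinom(n, 1, sm$female_frac[cohort])
  urban <- rbinom(n, 1, sm$urban_frac[cohort])
  edu_lab <- colnames(sm$edu_probs)
  education <- vapply(seq_len(n), function(i)
    sample(edu_lab, 1, prob = sm$edu_probs[cohort[i], ]), character(1))
  log_inc <- rnorm(n, sm$log_income_mean[cohort], sm$log_income_sd[cohort])
  income <- 10^log_inc
  no_spouse <- rbinom(n, 1, sm$no_spouse_frac[cohort])
  smoking <- rbinom(n, 1, sm$smoking_frac[cohort])
  drinking <- rbinom(n, 1, sm$drinking_frac[cohort])

  # disease onsets: inverse-CDF sampling on the discrete annual hazard,
  # curves shared within disease (hazards depend on age only)
  dp <- config$disease_params
  last_wave <- waves[K]
  ages_grid <- 45:(last_wave - min(birth_year))
  onset_year <- matrix(NA_real_, n, nrow(dp),
                       dimnames = list(NULL, dp$disease))
  for (k in seq_len(nrow(dp))) {
    h <- plogis(qlogis(dp$base_hazard[k]) + dp$age_slope[k] * (ages_grid - 60))
    Fcum <- 1 - cumprod(1 - h)
    u <- runif(n)
    pos <- findInterval(u, Fcum, left.open = TRUE) + 1L
    onset_age <- ifelse(pos <= length(ages_grid), ages_grid[pos], NA_real_)
    oy <- birth_year + onset_age
    oy[!is.na(oy) & oy > last_wave] <- NA_real_
    onset_year[, k] <- oy
  }

  # attrition: per-wave independent death / loss draws between waves
  at <- config$attrition
  exit_status <- rep("completed", n)
  exit_wave <- rep(waves[K], n)
  active <- rep(TRUE, n)
  if (K > 1) {
    for (w in 2:K) {
      die <- active & runif(n) < at$death_prob
      lose <- active & !die & runif(n) < at$loss_prob
      exit_status[die] <- "died"
      exit_status[lose] <- "lost"
      exit_wave[die | lose] <- waves[w - 1]
      active <- active & !die & !lose
    }
  }

  pid <- sprintf("p%06d", seq_len(n))
  rows <- do.call(rbind, lapply(seq_len(K), function(w) {
    keep <- exit_wave >= waves[w]
    data.frame(person_id = pid[keep], wave_year = waves[w],
               idx = which(keep), stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$person_id, rows$wave_year), ]
  i <- rows$idx

  panel <- data.frame(
    person_id = rows$person_id,
    wave_year = rows$wave_year,
    birth_year = birth_year[i],
    age = rows$wave_year - birth_year[i],
    female = female[i],
    residence = ifelse(urban[i] == 1, "urban", "rural"),
    education_raw = education[i],
    income_per_capita = income[i],
    marital = ifelse(no_spouse[i] == 1, "no_spouse", "spouse"),
    smoking = smoking[i],
    drinking = drinking[i],
    exit_status = exit_status[i],
    exit_wave = exit_wave[i],
    stringsAsFactors = FALSE
  )

  # wave-varying expenditures: lognormal amounts, beta out-of-pocket shares
  nr <- nrow(panel)
  hosp_ratio <- rbeta(nr, 2, 2)
  visit_ratio <- rbeta(nr, 2, 2)
  panel$hosp_total <- exp(rnorm(nr, 6.5, 1.2))
  panel$hosp_oop <- panel$hosp_total * hosp_ratio
  panel$visit_total <- exp(rnorm(nr, 4.5, 1.0))
  panel$visit_oop <- panel$visit_total * visit_ratio
  panel$hosp_oop_pct <- hosp_ratio
  panel$visit_oop_pct <- visit_ratio

  for (d in dp$disease) {
    oy <- onset_year[i, d]
    panel[[paste0("onset_", d)]] <- ifelse(!is.na(oy) & oy <= panel$wave_year,
                                           oy, NA_real_)
  }

  panel$vital <- "observed"
  is_last <- !duplicated(panel$person_id, fromLast = TRUE)
  exiting <- panel$exit_status != "completed"
  panel$vital[is_last & exiting] <- panel$exit_status[is_last & exiting]

  rownames(panel) <- NULL
  class(panel) <- c("panel_dataset", "data.frame")
  panel
}

#' Simulate growth-model outcomes on a coded design panel
#'
#' Mode-B simulation: attaches an outcome generated exactly from the
#' two-level model — fixed effects times the design row, plus person-level
#' random intercept/slope draws from the configured covariance, plus i.i.d.
#' Gaussian residuals. The outcome is not truncated at zero unless
#' `config$truncate_outcome` is set, matching the unconstrained Gaussian
#' model. When `config$attrition$outcome_coef` is nonzero, informative
#' dropout is superimposed: after each non-final wave a person dies with
#' probability `plogis(qlogis(death_prob) + outcome_coef * y)`, later rows
#' are dropped and the attrition dummy is recoded accordingly.
#'
#' @param config a [truth_config()] supplying `fixed_effects`, `random_cov`,
#'   `residual_var`, `truncate_outcome` and `attrition`.
#' @param coded a `coded_panel` from [code_panel()].
#' @param spec a [growth_spec()]; defaults to the spec matching
#'   `config$preset`.
#' @param outcome_name name of the outcome column to create.
#' @return the coded panel with the simulated outcome column and, under
#'   informative dropout, updated exit/attrition columns. True person-level
#'   random effects are attached as attribute `"random_effects"`.
#' @export
simulate_from_model <- function(config, coded, spec = NULL,
                                outcome_name = "dalys") {
  validate_truth_config(config)
  if (is.null(spec)) spec <- spec_from_preset(config$preset)
  des <- build_design(coded, spec, outcome_required = FALSE)
  beta_names <- colnames(des$X)
  missing <- setdiff(beta_names, names(config$fixed_effects))
  if (length(missing))
    stop("fixed_effects missing required term(s): ",
         paste(missing, collapse = ", "))
  beta <- config$fixed_effects[beta_names]

  q <- ncol(des$Z)
  Sig <- config$random_cov
  if (nrow(Sig) != q)
    stop("random_cov dimension ", nrow(Sig), " does not match random structure (q=", q, ")")

  persons <- des$persons
  J <- length(persons)
  ev <- eigen(Sig, symmetric = TRUE)           # PSD-safe factor (handles 0)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q)
  U <- matrix(rnorm(J * q), J, q) %*% t(L)   # person random effects
  rowU <- U[des$person_index, , drop = FALSE]
  mu <- as.numeric(des$X %*% beta)
  y <- mu + rowSums(des$Z * rowU) +
    rnorm(nrow(des$X), 0, sqrt(config$residual_var))
  if (isTRUE(config$truncate_outcome)) y <- pmax(y, 0)

  out <- des$data
  out[[outcome_name]] <- y

  oc <- config$attrition$outcome_coef
  if (!is.null(oc) && oc != 0) {
    # informative (MNAR) dropout: death before the wave-w interview depends
    # on the person's current, hence never-observed, outcome at wave w
    waves <- sort(unique(out$wave_year))
    K <- length(waves)
    base <- qlogis(min(max(config$attrition$death_prob, 1e-6), 1 - 1e-6))
    exit_wave <- stats::setNames(rep(waves[K], J), persons)
    died <- stats::setNames(rep(FALSE, J), persons)
    sel <- config$attrition$selection_on
    driver <- if (!is.null(sel) && sel == "expected") mu else out[[outcome_name]]
    for (w in 2:K) {
      rows <- which(out$wave_year == waves[w] &
                      exit_wave[out$person_id] == waves[K])
      p_die <- plogis(base + oc * driver[rows])
      hit <- runif(length(rows)) < p_die
      exit_wave[out$person_id[rows][hit]] <- waves[w - 1]
      died[out$person_id[rows][hit]] <- TRUE
    }
    keep <- out$wave_year <= exit_wave[out$person_id]
    out <- out[keep, , drop = FALSE]
    prior <- if ("died_or_lost" %in% names(out)) out$died_or_lost == 1 else FALSE
    out$died_or_lost <- as.integer(died[out$person_id] | prior)
    # terminal-decline elevation: persons selected out by death carry a
    # genuinely higher outcome trajectory (shared-frailty view of
    # informative dropout)
    de <- config$attrition$died_effect
    if (!is.null(de) && de != 0)
      out[[outcome_name]] <- out[[outcome_name]] + de * (died[out$person_id])
    if ("exit_status" %in% names(out))
      out$exit_status <- ifelse(died[out$person_id], "died", out$exit_status)
    attr(out, "informative_dropout") <- TRUE
  }
  rownames(out) <- NULL
  attr(out, "random_effects") <- U
  attr(out, "truth") <- list(fixed = beta, random_cov = Sig,
                             residual_var = config$residual_var)
  class(out) <- c("coded_panel", "data.frame")
  out
}
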