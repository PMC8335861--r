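make_fit_stub <- function(terms, estimates) {
  p <- length(terms)
  structure(list(
    fixed_effects = data.frame(term = terms, estimate = estimates,
                               se = 0, ci_lo = estimates, ci_hi = estimates,
                               p = NA, stringsAsFactors = FALSE),
    vcov_fixed = matrix(0, p, p, dimnames = list(terms, terms)),
    estimation = "ML"), class = "growth_fit")
}

test_that("all-zero coefficients give a flat zero trajectory", {
  fit <- make_fit_stub(c("(Intercept)", "age_c", "age_c2", "cohort"),
                       rep(0, 4))
  tg <- predict_trajectories(fit, data.frame(cohort = 1), level = NULL)
  expect_true(all(tg$pred == 0))
})

test_that("predictions equal an independent dot-product evaluation", {
  sim <- simulated_panel(n = 120, seed = 3, spec = slim_spec())
  fit <- fit_growth(sim, slim_spec(), se_random = FALSE)
  prof <- data.frame(cohort = 2, hukou_urban = 1, log_income = 4.3, female = 1)
  grid <- c(-5, 0, 5)
  tg <- predict_trajectories(fit, prof, age_c_grid = grid)
  beta <- setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  for (k in seq_along(grid)) {
    a <- grid[k]
    manual <- beta[["(Intercept)"]] + beta[["age_c"]] * a +
      beta[["age_c2"]] * a^2 +
      beta[["age_c:cohort"]] * a * prof$cohort +
      beta[["age_c2:cohort"]] * a^2 * prof$cohort +
      beta[["cohort"]] * prof$cohort +
      beta[["hukou_urban"]] * prof$hukou_urban +
      beta[["log_income"]] * prof$log_income +
      beta[["female"]] * prof$female
    expect_equal(tg$pred[k], unname(manual), tolerance = 1e-12)
  }
})

test_that("cohort slope gap at centered age zero is 3 times the age-cohort term", {
  # with truth coefficients the fitted mean is exact, so use a stub built
  # from the preset itself
  pr <- model_preset("model1")
  fit <- make_fit_stub(names(pr$fixed), unname(pr$fixed))
  prof <- data.frame(cohort = c(1, 4),
                     hukou_urban = 0, edu_illiterate = 0, edu_elementary = 0,
                     log_income = 0, female = 0, no_spouse = 0,
                     died_or_lost = 0, hosp_oop_pct = 0, visit_oop_pct = 0,
                     hosp_oop_q2 = 0, hosp_total_q2 = 0, visit_oop_q2 = 0,
                     visit_total_q2 = 0, smoking = 0, drinking = 0)
  h <- 1e-4
  tg <- predict_trajectories(fit, prof, age_c_grid = c(-h, h), level = NULL)
  slope1 <- diff(tg$pred[tg$label == "profile1"]) / (2 * h)
  slope4 <- diff(tg$pred[tg$label == "profile2"]) / (2 * h)
  expect_equal(slope4 - slope1, 3 * pr$fixed[["age_c:cohort"]],
               tolerance = 1e-6)
})

test_that("trajectories are exact quadratics with constant second differences", {
  sim <- simulated_panel(n = 150, seed = 7, spec = slim_spec())
  fit <- fit_growth(sim, slim_spec(), se_random = FALSE)
  step <- 0.5
  prof <- data.frame(cohort = 3, hukou_urban = 0, log_income = 4.3, female = 0)
  tg <- predict_trajectories(fit, prof, age_c_grid = seq(-6, 6, step),
                             level = NULL)
  d2 <- diff(tg$pred, differences = 2)
  beta <- setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  curv <- beta[["age_c2"]] + beta[["age_c2:cohort"]] * prof$cohort
  expect_equal(d2, rep(2 * curv * step^2, length(d2)), tolerance = 1e-10)
})

test_that("actual-age axis is restored from the cohort medians", {
  fit <- make_fit_stub(c("(Intercept)", "age_c", "age_c2", "cohort"),
                       c(1, 0.5, -0.01, -0.2))
  meds <- c(`1` = 68, `4` = 52)
  tg <- predict_trajectories(fit, data.frame(cohort = c(1, 4)),
                             age_c_grid = c(-2, 0, 2),
                             cohort_medians = meds, level = NULL)
  expect_equal(tg$age[tg$label == "profile1"], c(66, 68, 70))
  expect_equal(tg$age[tg$label == "profile2"], c(50, 52, 54))
})

test_that("gender strata partition the sample and are order-invariant", {
  sim <- simulated_panel(n = 250, seed = 11, spec = slim_spec())
  fm <- stratified_fit(sim, slim_spec(), "male", se_random = FALSE)
  ff <- stratified_fit(sim, slim_spec(), "female", se_random = FALSE)
  expect_equal(fm$n_obs + ff$n_obs, nrow(sim))
  expect_false("female" %in% fm$fixed_effects$term)
  # permuting rows changes nothing
  shuffled <- sim[sample(nrow(sim)), ]
  class(shuffled) <- class(sim)
  fm2 <- stratified_fit(shuffled, slim_spec(), "male", se_random = FALSE)
  expect_equal(fm2$fixed_effects$estimate, fm$fixed_effects$estimate,
               tolerance = 1e-8)
  expect_error(stratified_fit(sim[0, ], slim_spec(), "male"), "empty stratum")
})

test_that("identical truth for both genders gives matching stratum estimates", {
  sim <- simulated_panel(n = 1200, seed = 13, spec = slim_spec())
  fm <- stratified_fit(sim, slim_spec(), "male", se_random = FALSE)
  ff <- stratified_fit(sim, slim_spec(), "female", se_random = FALSE)
  bm <- setNames(fm$fixed_effects$estimate, fm$fixed_effects$term)
  bf <- setNames(ff$fixed_effects$estimate, ff$fixed_effects$term)
  sm <- setNames(fm$fixed_effects$se, fm$fixed_effects$term)
  sf <- setNames(ff$fixed_effects$se, ff$fixed_effects$term)
  for (tm in c("age_c", "age_c:cohort", "cohort")) {
    expect_lt(abs(bm[[tm]] - bf[[tm]]), 4 * sqrt(sm[[tm]]^2 + sf[[tm]]^2))
  }
})

test_that("descriptive table matches an independent group-by recomputation", {
  sim <- simulated_panel(n = 300, seed = 17, spec = slim_spec())
  tab <- descriptive_table(sim)
  for (co in 1:4) {
    dd <- sim[sim$cohort == co, ]
    for (w in sort(unique(sim$wave_year))) {
      x <- dd$dalys[dd$wave_year == w]
      row <- tab[tab$section == "disease_burden" &
                   tab$item == paste0("dalys_", w) & tab$cohort == co, ]
      expect_equal(row$mean, mean(x))
      expect_equal(row$sd, sd(x))
    }
    base <- dd[!duplicated(dd$person_id), ]
    row <- tab[tab$section == "female" & tab$item == "female" &
                 tab$cohort == co, ]
    expect_equal(row$n, sum(base$female == 1))
    expect_equal(row$pct, 100 * mean(base$female == 1))
  }
})

test_that("descriptive proportions sum to 100 within cohort and SD of n=1 is absent", {
  sim <- simulated_panel(n = 200, seed = 19, spec = slim_spec())
  tab <- descriptive_table(sim)
  for (co in c(as.character(1:4), "all")) {
    for (sec in c("female", "hukou_urban", "education", "smoking")) {
      pct <- tab$pct[tab$section == sec & tab$cohort == co]
      expect_equal(sum(pct), 100, tolerance = 1e-9)
    }
  }
  one <- sim[1, , drop = FALSE]
  class(one) <- class(sim)
  t1 <- descriptive_table(one)
  row <- t1[t1$section == "disease_burden" & t1$cohort == "all" & t1$n == 1, ]
  expect_true(all(is.na(row$sd)))
})

test_that("within-cohort mean DALYs are non-decreasing across waves", {
  cfg <- truth_config(n_individuals = 1500, seed = 23,
                      attrition = list(death_prob = 0, loss_prob = 0,
                                       outcome_coef = 0))
  p <- generate_panel(cfg)
  p$dalys <- score_panel(p)$dalys
  tab <- descriptive_table(code_panel(p))
  for (co in as.character(1:4)) {
    m <- tab$mean[tab$section == "disease_burden" & tab$cohort == co]
    expect_true(all(diff(m) >= -1e-9))
  }
})
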