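test_that("noise-free data is interpolated exactly", {
  cfg <- small_config(n = 60, seed = 3, random_cov = matrix(0, 2, 2),
                      residual_var = 0)
  cp <- code_panel(generate_panel(cfg))
  sim <- simulate_from_model(cfg, cp, spec = slim_spec())
  fit <- fit_growth(sim, slim_spec(), se_random = FALSE)
  truth <- cfg$fixed_effects[fit$fixed_effects$term]
  expect_equal(fit$fixed_effects$estimate, unname(truth), tolerance = 1e-6)
})

test_that("estimates match the lme4 oracle on small instances", {
  skip_if_not_installed("lme4")
  for (seed in c(101, 202, 303)) {
    sim <- simulated_panel(n = 80, seed = seed, spec = slim_spec())
    des <- build_design(sim, slim_spec())
    fit <- fit_growth(des, se_random = FALSE)
    orc <- lme4_oracle(des)
    denom <- pmax(abs(orc$fixed), 0.1)
    expect_lt(max(abs(fit$fixed_effects$estimate - orc$fixed) / denom), 1e-4)
    expect_lt(abs(fit$random_cov[1, 1] - orc$var_intercept) /
                max(orc$var_intercept, 0.1), 1e-3)
    expect_lt(abs(fit$residual_var - orc$residual) /
                max(orc$residual, 0.1), 1e-3)
    expect_lt(abs(fit$neg2ll - orc$deviance), 1e-4)
  }
})

test_that("information criteria follow the stated counting convention", {
  sim <- simulated_panel(n = 100, seed = 7, spec = slim_spec())
  fit <- fit_growth(sim, slim_spec(), se_random = FALSE)
  k <- nrow(fit$fixed_effects) + 3 + 1
  expect_equal(fit$aic, fit$neg2ll + 2 * k)
  expect_equal(fit$bic, fit$neg2ll + log(fit$n_obs) * k)
  expect_true(fit$converged)
  expect_true(all(fit$fixed_effects$ci_lo < fit$fixed_effects$estimate))
  expect_true(all(fit$fixed_effects$ci_hi > fit$fixed_effects$estimate))
  # Wald CI symmetry
  expect_equal(fit$fixed_effects$estimate - fit$fixed_effects$ci_lo,
               fit$fixed_effects$ci_hi - fit$fixed_effects$estimate)
})

test_that("estimated random covariance is positive semi-definite", {
  sim <- simulated_panel(n = 150, seed = 13, spec = slim_spec())
  fit <- fit_growth(sim, slim_spec())
  ev <- eigen(fit$random_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) >= -1e-10)
  expect_gt(fit$residual_var, 0)
  expect_false(is.null(fit$random_se))
  expect_true(all(diag(fit$random_se) > 0))
})

test_that("nested ML fits have monotone -2LL and comparisons refuse REML", {
  sim <- simulated_panel(n = 200, seed = 17, preset = "model3",
                         spec = spec_from_preset("model3"))
  quad <- fit_growth(sim, spec_from_preset("model3"), se_random = FALSE)
  lin_spec <- spec_from_preset("model3")
  lin_spec$quadratic <- FALSE
  lin_spec$curvature_moderators <- character(0)
  lin <- fit_growth(sim, lin_spec, se_random = FALSE)
  expect_lte(quad$neg2ll, lin$neg2ll + 1e-6)
  cmp <- compare_fits(list(quadratic = quad, linear = lin))
  expect_equal(cmp$delta_neg2ll[cmp$model == "quadratic"], 0)
  # identical fits give zero deltas
  cmp2 <- compare_fits(list(a = quad, b = quad))
  expect_true(all(cmp2$delta_aic == 0) && all(cmp2$delta_bic == 0))
  # REML with different fixed parts is refused
  r1 <- quad; r1$estimation <- "REML"
  r2 <- lin; r2$estimation <- "REML"
  expect_error(compare_fits(list(r1, r2)), "REML")
})

test_that("REML estimation runs and shrinks less than ML", {
  spec_reml <- slim_spec()
  spec_reml$estimation <- "REML"
  sim <- simulated_panel(n = 120, seed = 19, spec = slim_spec())
  ml <- fit_growth(sim, slim_spec(), se_random = FALSE)
  reml <- fit_growth(sim, spec_reml, se_random = FALSE)
  expect_identical(reml$estimation, "REML")
  # REML residual variance is at least the ML one in expectation; here just
  # check both are positive and close
  expect_gt(reml$residual_var, 0)
  expect_lt(abs(reml$residual_var - ml$residual_var) / ml$residual_var, 0.2)
})

test_that("fixed effects are invariant to the centering constant as predicted", {
  spec <- growth_spec(slope_moderators = character(0),
                      curvature_moderators = character(0),
                      intercept_covariates = "cohort")
  cfg <- small_config(n = 250, seed = 23)
  cp <- code_panel(generate_panel(cfg))
  sim <- simulate_from_model(cfg, cp, spec = spec)
  f0 <- fit_growth(sim, spec, se_random = FALSE)
  shift <- 3
  sim2 <- sim
  sim2$age_c <- sim$age_c + shift
  sim2$age_c2 <- sim2$age_c^2
  f1 <- fit_growth(sim2, spec, se_random = FALSE)
  b0 <- setNames(f0$fixed_effects$estimate, f0$fixed_effects$term)
  b1 <- setNames(f1$fixed_effects$estimate, f1$fixed_effects$term)
  # curvature unchanged; slope and intercept shift analytically
  expect_equal(b1[["age_c2"]], b0[["age_c2"]], tolerance = 1e-6)
  expect_equal(b1[["age_c"]], b0[["age_c"]] - 2 * b0[["age_c2"]] * shift,
               tolerance = 1e-5)
  expect_equal(b1[["(Intercept)"]],
               b0[["(Intercept)"]] - b0[["age_c"]] * shift +
                 b0[["age_c2"]] * shift^2,
               tolerance = 1e-4)
  expect_equal(b1[["cohort"]], b0[["cohort"]], tolerance = 1e-5)
})

test_that("fit tables export to CSV in the published layout", {
  sim <- simulated_panel(n = 80, seed = 29, spec = slim_spec())
  fit <- fit_growth(sim, slim_spec())
  path <- withr::local_tempfile(fileext = ".csv")
  write_fit_csv(fit, path)
  back <- read.csv(path)
  expect_true(all(c("var_intercept", "var_slope", "covariance", "residual",
                    "neg2ll", "aic", "bic") %in% back$term))
  expect_equal(back$estimate[back$term == "residual"], fit$residual_var,
               tolerance = 1e-9)
})
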