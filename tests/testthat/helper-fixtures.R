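# Shared fixtures: small panels and slim model specs used across tests.

small_config <- function(n = 300, seed = 1, ...) {
  truth_config(n_individuals = n, seed = seed, ...)
}

# slim spec with few covariates, for fast fits against the lme4 oracle
slim_spec <- function(quadratic = TRUE) {
  growth_spec(slope_moderators = "cohort",
              curvature_moderators = "cohort",
              intercept_covariates = c("cohort", "hukou_urban",
                                       "log_income", "female"),
              quadratic = quadratic)
}

# simulate a coded panel with outcome from a config (mode A covariates +
# mode B outcome), with independent seeds for design and outcome
simulated_panel <- function(n = 300, seed = 1, preset = "model1",
                            spec = NULL, sim_seed = seed + 1000, ...) {
  cfg <- truth_config(n_individuals = n, seed = seed, preset = preset, ...)
  p <- generate_panel(cfg)
  cp <- code_panel(p)
  set.seed(sim_seed)
  simulate_from_model(cfg, cp, spec = spec)
}

# independent lme4 fit on a built design (cross-implementation oracle)
lme4_oracle <- function(des) {
  df <- data.frame(y = des$y, pid = des$data$person_id,
                   age_c = des$data$age_c)
  Xo <- des$X
  fit <- lme4::lmer(y ~ 0 + Xo + (1 + age_c | pid), data = df, REML = FALSE,
                    control = lme4::lmerControl(
                      calc.derivs = FALSE, optimizer = "bobyqa",
                      optCtrl = list(rhoend = 1e-10)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(fixed = stats::setNames(lme4::fixef(fit), colnames(des$X)),
       var_intercept = vc$vcov[vc$var1 == "(Intercept)" & is.na(vc$var2)][1],
       var_slope = vc$vcov[vc$var1 == "age_c" & is.na(vc$var2)][1],
       covariance = vc$vcov[!is.na(vc$var2)][1],
       residual = vc$vcov[vc$grp == "Residual"][1],
       deviance = stats::deviance(fit))
}
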