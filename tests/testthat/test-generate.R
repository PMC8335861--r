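test_that("empty and degenerate configurations behave as specified", {
  empty <- generate_panel(small_config(n = 0))
  expect_equal(nrow(empty), 0L)
  dp <- default_disease_params()
  dp$base_hazard[] <- 0
  p <- generate_panel(small_config(n = 50, seed = 2, disease_params = dp))
  expect_true(all(is.na(as.matrix(p[grep("^onset_", names(p))]))))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(truth_config(cohort_mix = c(0.5, 0.5, 0.2, 0.1)), "cohort_mix")
  expect_error(truth_config(attrition = list(death_prob = 0.9, loss_prob = 0.3,
                                             outcome_coef = 0)), "attrition")
  expect_error(truth_config(residual_var = -1), "residual_var")
  expect_error(truth_config(random_cov = matrix(c(1, 2, 2, 1), 2)),
               "positive semi-definite")
})

test_that("panel rows satisfy the person-wave invariants", {
  p <- generate_panel(small_config(n = 400, seed = 31,
                                   attrition = list(death_prob = 0.04,
                                                    loss_prob = 0.03,
                                                    outcome_coef = 0)))
  expect_true(all(p$age == p$wave_year - p$birth_year))
  expect_true(all(p$age >= 45 & p$age <= 90))
  # ordered, no duplicate waves per person
  key <- paste(p$person_id, p$wave_year)
  expect_false(any(duplicated(key)))
  # once exited, no later record
  agg <- aggregate(wave_year ~ person_id + exit_wave, data = p, FUN = max)
  expect_true(all(agg$wave_year <= agg$exit_wave))
  # onset years never exceed the wave that reports them
  for (oc in grep("^onset_", names(p), value = TRUE)) {
    v <- p[[oc]]
    expect_true(all(is.na(v) | v <= p$wave_year))
  }
})

test_that("onsets are absorbing: the onset year never changes once reported", {
  p <- generate_panel(small_config(n = 300, seed = 37))
  for (oc in grep("^onset_", names(p), value = TRUE)) {
    n_distinct <- tapply(p[[oc]], p$person_id,
                         function(v) length(unique(v[!is.na(v)])))
    expect_true(all(unlist(n_distinct) <= 1))
  }
})

test_that("retention under per-wave loss matches the binomial expectation", {
  loss <- 0.03
  n <- 10000
  p <- generate_panel(truth_config(
    n_individuals = n, seed = 43,
    attrition = list(death_prob = 0, loss_prob = loss, outcome_coef = 0)))
  waves <- sort(unique(p$wave_year))
  for (w in seq_along(waves)) {
    expected <- n * (1 - loss)^(w - 1)
    se <- sqrt(n * (1 - loss)^(w - 1) * (1 - (1 - loss)^(w - 1)))
    observed <- sum(p$wave_year == waves[w])
    if (w == 1) expect_equal(observed, n)
    else expect_lt(abs(observed - expected), 3 * se)
  }
})

test_that("generation is byte-identical under the same seed", {
  cfg <- small_config(n = 200, seed = 51)
  expect_identical(generate_panel(cfg), generate_panel(cfg))
  cfg2 <- small_config(n = 200, seed = 52)
  expect_false(identical(generate_panel(cfg), generate_panel(cfg2)))
})

test_that("noise-free model simulation is an exact quadratic in centered age", {
  cfg <- small_config(n = 80, seed = 61, random_cov = matrix(0, 2, 2),
                      residual_var = 0)
  cp <- code_panel(generate_panel(cfg))
  sim <- simulate_from_model(cfg, cp, spec = slim_spec())
  des <- build_design(sim, slim_spec())
  beta <- cfg$fixed_effects[colnames(des$X)]
  expect_equal(des$y, as.numeric(des$X %*% beta), tolerance = 1e-12)
})

test_that("pure-noise simulation has mean 0 and variance 1", {
  cfg <- small_config(n = 3000, seed = 67, random_cov = matrix(0, 2, 2),
                      residual_var = 1)
  cfg$fixed_effects[] <- 0
  cp <- code_panel(generate_panel(cfg))
  sim <- simulate_from_model(cfg, cp, spec = slim_spec())
  y <- sim$dalys
  expect_lt(abs(mean(y)), 3 / sqrt(length(y)))
  expect_lt(abs(var(y) - 1), 5 * sqrt(2 / length(y)))
})

test_that("simulation fails listing missing fixed-effect terms", {
  cfg <- small_config(n = 50, seed = 71)
  cfg$fixed_effects <- cfg$fixed_effects[
    setdiff(names(cfg$fixed_effects), "cohort")]
  cp <- code_panel(generate_panel(cfg))
  expect_error(simulate_from_model(cfg, cp, spec = slim_spec()), "cohort")
})

test_that("marginal outcome variance follows the mixed-model closed form", {
  cfg <- truth_config(n_individuals = 6000, seed = 73)
  cp <- code_panel(generate_panel(cfg))
  sim <- simulate_from_model(cfg, cp)
  des <- build_design(sim, spec_from_preset("model1"))
  beta <- cfg$fixed_effects[colnames(des$X)]
  resid <- des$y - as.numeric(des$X %*% beta)
  S <- cfg$random_cov
  a <- round(des$data$age_c)
  for (aa in c(-4, 0, 4)) {
    idx <- which(a == aa)
    theo <- S[1, 1] + 2 * aa * S[1, 2] + aa^2 * S[2, 2] + cfg$residual_var
    emp <- var(resid[idx])
    # sampling error of a variance over ~thousands of draws
    expect_lt(abs(emp - theo) / theo, 4 * sqrt(2 / length(idx)))
  }
})

test_that("cohort-conditional means at centered age zero match closed form", {
  cfg <- truth_config(n_individuals = 8000, seed = 79)
  cp <- code_panel(generate_panel(cfg))
  sim <- simulate_from_model(cfg, cp)
  des <- build_design(sim, spec_from_preset("model1"))
  beta <- cfg$fixed_effects[colnames(des$X)]
  # at rows with age_c == 0 the mean equals the non-age part of X beta
  idx <- which(des$data$age_c == 0)
  mu <- as.numeric(des$X[idx, , drop = FALSE] %*% beta)
  y <- des$y[idx]
  sdy <- sqrt(cfg$random_cov[1, 1] + cfg$residual_var)
  expect_lt(abs(mean(y - mu)), 4 * sdy / sqrt(length(idx)))
})
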