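test_that("cohort assignment follows the configured boundaries", {
  expect_equal(assign_cohort(c(1944, 1950, 1955, 1962)), c(1L, 2L, 3L, 4L))
  expect_warning(out <- assign_cohort(1941), "outside")
  expect_true(is.na(out))
  # the two published boundary sets disagree on 1947
  expect_equal(assign_cohort(1947, cohort_breaks("table")), 1L)
  expect_equal(assign_cohort(1947, cohort_breaks("alternative")), 2L)
  expect_equal(assign_cohort(1964), 4L)
})

test_that("age centering subtracts the cohort median", {
  cen <- center_age(c(50, 60, 70), c(1, 1, 1))
  expect_equal(cen$age_c, c(-10, 0, 10))
  expect_equal(cen$age_c2, c(100, 0, 100))
  cen2 <- center_age(rep(63, 5), rep(2, 5))
  expect_true(all(cen2$age_c == 0))
})

test_that("cohort medians match an independent sort-based oracle", {
  cfg <- small_config(n = 500, seed = 5)
  p <- generate_panel(cfg)
  cp <- code_panel(p)
  meds <- attr(cp, "codebook")$age_centering$cohort_medians
  for (co in 1:4) {
    ages <- sort(cp$age[cp$cohort == co])
    oracle <- ages[ceiling(length(ages) / 2)]   # lower median by sorting
    expect_equal(meds[[as.character(co)]], oracle)
    expect_equal(cp$age_c[cp$cohort == co],
                 cp$age[cp$cohort == co] - oracle)
  }
  expect_equal(cp$age_c2, cp$age_c^2)
})

test_that("income is log10 with a positive floor", {
  p <- generate_panel(small_config(n = 50, seed = 9))
  p$income_per_capita[1] <- 20000
  p$income_per_capita[2] <- 0
  cp <- code_panel(p)
  expect_equal(cp$log_income[1], log10(20000), tolerance = 1e-12)
  expect_equal(cp$log_income[2], 0) # floored at 1 then log10
})

test_that("expenditure median split assigns ties upward", {
  p <- generate_panel(small_config(n = 101, seed = 13))
  med <- quantile(p$hosp_oop, 0.5, type = 1)
  p$hosp_oop[1] <- med
  cp <- code_panel(p)
  expect_equal(cp$hosp_oop_q2[1], 1L)
  expect_equal(cp$hosp_oop_q2, as.integer(p$hosp_oop >= med))
})

test_that("attrition dummy marks every record of exiting persons", {
  cfg <- small_config(n = 400, seed = 17,
                      attrition = list(death_prob = 0.05, loss_prob = 0.05,
                                       outcome_coef = 0))
  p <- generate_panel(cfg)
  cp <- code_panel(p)
  per <- tapply(cp$died_or_lost, cp$person_id, unique)
  expect_true(all(lengths(per) == 1)) # constant within person
  completers <- unique(p$person_id[p$exit_status == "completed"])
  expect_true(all(cp$died_or_lost[cp$person_id %in% completers] == 0))
  exiters <- unique(p$person_id[p$exit_status != "completed"])
  expect_true(all(cp$died_or_lost[cp$person_id %in% exiters] == 1))
  # split option
  cps <- code_panel(p, split_attrition = TRUE)
  expect_true(all(c("died", "lost") %in% names(cps)))
  expect_equal(cps$died + cps$lost, cp$died_or_lost)
})

test_that("education is time-constant at the baseline value", {
  p <- generate_panel(small_config(n = 100, seed = 19))
  # inject a within-person change after baseline
  pid <- p$person_id[duplicated(p$person_id)][1]
  rows <- which(p$person_id == pid)
  p$education_raw[rows[-1]] <- "illiterate"
  p$education_raw[rows[1]] <- "middle_or_higher"
  cp <- code_panel(p)
  expect_true(all(cp$edu_illiterate[cp$person_id == pid] == 0))
  expect_true(all(cp$edu_elementary[cp$person_id == pid] == 0))
  expect_gte(attr(cp, "codebook")$education$collapsed_records, 1)
})

test_that("stored cohort is consistent with birth year on every row", {
  cp <- code_panel(generate_panel(small_config(n = 300, seed = 23)))
  expect_equal(cp$cohort, assign_cohort(cp$birth_year))
  expect_true(all(cp$cohort %in% 1:4))
})

test_that("coding is deterministic and reference level never appears", {
  p <- generate_panel(small_config(n = 200, seed = 29))
  c1 <- code_panel(p)
  c2 <- code_panel(p)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_false(any(grepl("middle", names(c1))))
})
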