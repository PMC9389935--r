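test_that("invalid configurations are rejected with the field named", {
  expect_error(synth_config(n_hospitals = 0), "n_hospitals")
  expect_error(synth_config(admissions_per_year_range = c(500L, 100L)),
               "admissions_per_year_range")
  expect_error(synth_config(p_ischemic = 1.2), "p_ischemic")
  expect_error(synth_config(stage_time_priors = list(
    onset_to_arrival = list(mu = c(5, 4), sigma = c(0.9, 1.2)),
    arrival_to_scan = list(mu = c(3, 4), sigma = c(0.6, 1)),
    scan_to_needle = list(mu = c(3, 3.5), sigma = c(0.4, 0.6))
  )), "onset_to_arrival")
  expect_error(synth_config(treatment_window = 100), "treatment_window")
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- synth_config(n_hospitals = 4, years = 1,
                      admissions_per_year_range = c(80L, 120L), seed = 33)
  h1 <- generate_hospitals(cfg)
  h2 <- generate_hospitals(cfg)
  expect_identical(h1, h2)
  p1 <- generate_patients(h1, cfg)
  p2 <- generate_patients(h2, cfg)
  expect_identical(p1, p2)
  # per-hospital substreams: a hospital's patients do not depend on which
  # other hospitals are generated alongside it
  p_sub <- generate_patients(h1[2, ], cfg)
  expect_equal(as.data.frame(p_sub),
               as.data.frame(p1[p1$hospital_id == h1$hospital_id[2], ]),
               ignore_attr = TRUE)
})

test_that("patient records respect the schema invariants", {
  sys <- small_system(n_hospitals = 5, admissions = 300L, seed = 17)
  pat <- sys$patients
  cfg <- sys$config
  expect_equal(nrow(pat), sum(sys$hospitals$admissions_per_year) * cfg$years)
  # onset-to-arrival undefined exactly when onset unknown
  expect_true(all(is.na(pat$t_oa) == (pat$onset_known == 0)))
  # scan-to-needle recorded only for the treated
  expect_true(all(is.na(pat$t_sn) == (pat$thrombolysis == 0)))
  # defined times positive, never zero-coded
  expect_true(all(pat$t_oa[!is.na(pat$t_oa)] >= 1))
  expect_true(all(pat$t_as[!is.na(pat$t_as)] >= 1))
  expect_true(all(pat$nihss >= 0 & pat$nihss <= 42))
  expect_true(all(pat$prestroke_mrs %in% 0:5))
  # treatment implies ischaemic, known onset, scan in window, needle in window
  tr <- pat[pat$thrombolysis == 1, ]
  expect_true(all(tr$ischemic == 1))
  expect_true(all(tr$onset_known == 1))
  expect_true(all(tr$t_oa + tr$t_as <= cfg$eligibility_window))
  expect_true(all(tr$t_oa + tr$t_as + tr$t_sn <= cfg$treatment_window))
  # eligibility conservation at the whole-table level
  eligible <- pat$onset_known == 1 & pat$ischemic == 1 & !is.na(pat$t_as) &
    (pat$t_oa + pat$t_as) <= cfg$eligibility_window
  expect_lte(sum(pat$thrombolysis), sum(eligible, na.rm = TRUE))
})

test_that("no patients are treated when onset is never known", {
  cfg <- synth_config(n_hospitals = 1, years = 1,
                      admissions_per_year_range = c(200L, 200L),
                      p_onset_known_shape = c(1, 1), seed = 3)
  h <- generate_hospitals(cfg)
  h$p_onset_known <- 0
  pat <- generate_patients(h, cfg)
  expect_equal(sum(pat$thrombolysis), 0)
  expect_true(all(is.na(pat$t_oa)))
})

test_that("an unobstructed pathway treats exactly the ischaemic share", {
  # degenerate zero-variance instant pathway, decision probability ~1 for
  # ischaemic strokes: treated fraction must match p_ischemic binomially
  cfg <- synth_config(
    n_hospitals = 1, years = 1, admissions_per_year_range = c(20000L, 20000L),
    p_missing_scan = 0,
    decision_coefficients = c(intercept = 50, severity = 0,
                              onset_precise = 0, age_80plus = 0,
                              anticoagulant = 0, prestroke_mrs = 0,
                              onset_to_arrival_hr = 0),
    hospital_intercept_sd = 0, seed = 5
  )
  h <- generate_hospitals(cfg)
  h$p_onset_known <- 1
  h$mu_oa <- log(1); h$sigma_oa <- 0
  h$mu_as <- log(1); h$sigma_as <- 0
  h$mu_sn <- log(1); h$sigma_sn <- 0
  pat <- generate_patients(h, cfg)
  n <- nrow(pat)
  se <- sqrt(cfg$p_ischemic * (1 - cfg$p_ischemic) / n)
  expect_lt(abs(mean(pat$thrombolysis) - cfg$p_ischemic), 3 * se)
})

test_that("the per-patient loop oracle handles its analytic cases", {
  cfg <- constant_decision_config(intercept = -50, seed = 9)
  h <- truth_row(decision_intercept = -50)
  expect_equal(ground_truth_rate(h, cfg, 500, seed = 1), 0)

  # all-instant pathway, onset known half the time, decision certain:
  # treated fraction is p_onset_known
  cfg2 <- constant_decision_config(intercept = 50, seed = 9)
  h2 <- truth_row(p_onset_known = 0.5, mu_oa = 0, sigma_oa = 0,
                  mu_as = 0, sigma_as = 0, mu_sn = 0, sigma_sn = 0,
                  decision_intercept = 50)
  n <- 20000
  r <- ground_truth_rate(h2, cfg2, n, seed = 2)
  expect_lt(abs(r - 0.5), 3 * sqrt(0.25 / n))
})

test_that("generated treated fractions agree with the loop oracle", {
  cfg <- constant_decision_config(intercept = 0.8, n_hospitals = 1,
                                  years = 1,
                                  admissions_per_year_range = c(30000L,
                                                                30000L),
                                  seed = 23)
  h <- generate_hospitals(cfg)
  pat <- generate_patients(h, cfg)
  gt <- ground_truth_rate(h, cfg, 30000, seed = 77)
  p <- (mean(pat$thrombolysis) + gt) / 2
  se <- sqrt(p * (1 - p) * 2 / 30000)
  expect_lt(abs(mean(pat$thrombolysis) - gt), 3 * se)
})

test_that("patient tables round-trip through the CSV schema", {
  sys <- small_system(n_hospitals = 2, admissions = 150L, seed = 29)
  path <- withr::local_tempfile(fileext = ".csv")
  write_patients(sys$patients, path)
  # missing values are empty fields, never zeros
  first_lines <- readLines(path, n = 5)
  expect_match(first_lines[1], "^hospital_id,patient_id,")
  back <- read_patients(path)
  expect_equal(as.data.frame(back), as.data.frame(sys$patients))
  expect_error(write_patients(sys$patients[, -3], path), "onset_known")
})

test_that("generator configurations round-trip through YAML", {
  cfg <- synth_config(n_hospitals = 7, seed = 101,
                      p_onset_known_shape = c(12, 6))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_synth_config(cfg, path)
  back <- read_synth_config(path)
  expect_equal(back, cfg)
  writeLines("bogus_field: 3", path)
  expect_error(read_synth_config(path), "bogus_field")
})

test_that("shipped defaults reproduce the national audit's statistical shape", {
  cfg <- synth_config() # default seed
  hospitals <- generate_hospitals(cfg)
  pat <- generate_patients(hospitals, cfg)
  pooled <- mean(pat$thrombolysis)
  expect_gt(pooled, 0.10)
  expect_lt(pooled, 0.13)
  expect_lt(abs(pooled - 0.116), 0.01)
  rates <- tapply(pat$thrombolysis, pat$hospital_id, mean)
  # hospital-level use spans at least 5%-25%
  expect_lte(min(rates), 0.05)
  expect_gte(max(rates), 0.25)
  expect_gte(max(rates) / min(rates), 5)
  # ~37% of admissions arrive within 4 h of a known onset
  within4h <- mean(pat$onset_known == 1 & !is.na(pat$t_oa) &
                     pat$t_oa <= 240)
  expect_lt(abs(within4h - 0.37), 0.03)
  # about two thirds of onset times are determined
  expect_lt(abs(mean(pat$onset_known) - 2 / 3), 0.05)
})
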