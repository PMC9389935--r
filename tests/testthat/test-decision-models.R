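test_that("the sensitivity=specificity crossing matches a brute-force sweep", {
  # independent oracle: evaluate both curves on a dense threshold grid and
  # report the common value where they meet, interpolating linearly
  brute_crossing <- function(probs, labels) {
    sens_at <- function(t) mean(probs[labels == 1] >= t)
    spec_at <- function(t) mean(probs[labels == 0] < t)
    grid <- sort(unique(c(0, probs, 1)))
    best <- NULL
    for (i in seq_len(length(grid) - 1)) {
      d1 <- sens_at(grid[i]) - spec_at(grid[i])
      d2 <- sens_at(grid[i + 1]) - spec_at(grid[i + 1])
      if (d1 > 0 && d2 <= 0) {
        a <- d1 / (d1 - d2)
        best <- sens_at(grid[i]) +
          a * (sens_at(grid[i + 1]) - sens_at(grid[i]))
        break
      }
    }
    if (is.null(best)) best <- sens_at(grid[1])
    best
  }
  # hand-built 8-point probability vector
  probs <- c(0.05, 0.2, 0.3, 0.45, 0.55, 0.6, 0.8, 0.9)
  labels <- c(0, 0, 1, 0, 1, 0, 1, 1)
  expect_equal(sens_spec_crossing(probs, labels),
               brute_crossing(probs, labels))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(40)
    y <- rbinom(40, 1, p)
    if (length(unique(y)) < 2) next
    expect_equal(sens_spec_crossing(p, y), brute_crossing(p, y))
  }
  expect_error(sens_spec_crossing(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("a constant-label hospital yields a constant model", {
  sys <- small_system(n_hospitals = 1, admissions = 150L, seed = 41)
  pat <- sys$patients
  pat$thrombolysis <- 0
  pat$t_sn <- NA_real_
  m <- train_hospital_model(pat, pat$hospital_id[1], seed = 1)
  expect_equal(predict_treatment(m, ml_eligible(pat)),
               rep(0L, nrow(ml_eligible(pat))))
  expect_error(train_hospital_model(pat[1:30, ], pat$hospital_id[1]),
               "eligible training patients")
})

test_that("model training is deterministic and learns a planted rule", {
  sys <- small_system(n_hospitals = 1, admissions = 520L, seed = 43)
  id <- sys$hospitals$hospital_id[1]
  m1 <- train_hospital_model(sys$patients, id, seed = 9)
  m2 <- train_hospital_model(sys$patients, id, seed = 9)
  ml <- ml_eligible(sys$patients)
  expect_identical(predict_treatment_prob(m1, ml),
                   predict_treatment_prob(m2, ml))
  ev <- evaluate_model(m1, sys$patients, k = 5)
  expect_gte(ev$accuracy, 0.80)
  expect_gte(ev$roc_auc, 0.85)
  expect_true(ev$sens_eq_spec >= 0 && ev$sens_eq_spec <= 1)
  expect_error(predict_treatment_prob(m1, ml[, -which(names(ml) == "nihss")]),
               "nihss")
})

test_that("cross-validated AUC of an uninformative signal is ~0.5", {
  # scoring by a fair coin on balanced labels: rank AUC near 1/2
  set.seed(19)
  n <- 2000
  p <- runif(n)
  y <- rep(c(0, 1), n / 2)
  auc <- strokepathsim:::rank_auc(p, y)
  expect_lt(abs(auc - 0.5), 3 * sqrt(1 / (12 * n / 4)))
  # and the rank statistic agrees with an independent ROC implementation
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc, ref, tolerance = 1e-12)
})

test_that("perfectly separable data scores perfectly", {
  probs <- c(rep(0.1, 10), rep(0.9, 10))
  labels <- c(rep(0, 10), rep(1, 10))
  expect_equal(strokepathsim:::rank_auc(probs, labels), 1)
  expect_equal(sens_spec_crossing(probs, labels), 1)
  expect_equal(mean((probs >= 0.5) == (labels == 1)), 1)
})

test_that("cohorts are fixed-seed samples disjoint from training rows", {
  sys <- small_system(n_hospitals = 3, admissions = 300L, seed = 47)
  pat <- sys$patients
  hold <- holdout_split(pat, prop = 0.25, seed = 5)
  c1 <- build_cohort(pat, 200, hold, seed = 6)
  c2 <- build_cohort(pat, 200, hold, seed = 6)
  expect_identical(c1$patient_id, c2$patient_id)
  expect_equal(nrow(build_cohort(pat, 0, hold)), 0)
  expect_error(build_cohort(pat, 1e6, hold), "held-out")
  # training explicitly excludes the holdout: intersection must be empty
  m <- train_hospital_model(pat, sys$hospitals$hospital_id[1],
                            exclude_ids = hold, seed = 1)
  ml <- ml_eligible(pat)
  train_ids <- setdiff(ml$patient_id[ml$hospital_id ==
                                       sys$hospitals$hospital_id[1]], hold)
  expect_length(intersect(c1$patient_id, train_ids), 0)
  expect_equal(m$training_size, length(train_ids))
})

test_that("benchmark selection takes the top cohort rates, order-free", {
  # hand-built constant models with known cohort rates
  mk_const <- function(id, p) {
    structure(list(hospital_id = id, fit = NULL,
                   constant = if (p >= 0.5) "yes" else "no",
                   features = strokepathsim:::decision_features,
                   training_size = 100, seed = 1, num_trees = 100),
              class = "decision_model")
  }
  cohort <- ml_eligible(small_system(n_hospitals = 1, admissions = 100L,
                                     seed = 51)$patients)
  models <- list(mk_const("A", 1), mk_const("B", 0), mk_const("C", 1),
                 mk_const("D", 0))
  b2 <- select_benchmark(models, cohort, n_benchmark = 2)
  expect_setequal(b2$members, c("A", "C")) # ties broken by hospital id
  expect_equal(b2$members, c("A", "C"))
  b2r <- select_benchmark(rev(models), cohort, n_benchmark = 2)
  expect_equal(b2r$members, b2$members)
  # with exactly n models, all are selected regardless of rates
  ball <- select_benchmark(models, cohort, n_benchmark = 4)
  expect_setequal(ball$members, c("A", "B", "C", "D"))
  expect_error(select_benchmark(models, cohort, n_benchmark = 5),
               "benchmark hospitals requested")
})

test_that("the majority vote needs a strict majority and is monotone", {
  mk_const <- function(id, yes) {
    structure(list(hospital_id = id, fit = NULL,
                   constant = if (yes) "yes" else "no",
                   features = strokepathsim:::decision_features,
                   training_size = 100, seed = 1, num_trees = 100),
              class = "decision_model")
  }
  cohort <- ml_eligible(small_system(n_hospitals = 1, admissions = 100L,
                                     seed = 51)$patients)[1:4, ]
  vote_with <- function(n_yes, n_total = 30) {
    models <- c(lapply(seq_len(n_yes), function(i) {
      mk_const(sprintf("Y%02d", i), TRUE)
    }), lapply(seq_len(n_total - n_yes), function(i) {
      mk_const(sprintf("N%02d", i), FALSE)
    }))
    bench <- structure(list(members = vapply(models, `[[`, "",
                                             "hospital_id"),
                            models = models, cohort_rates = NULL),
                       class = "benchmark_set")
    benchmark_decide(bench, cohort)
  }
  expect_equal(vote_with(30), rep(1L, 4))  # unanimous yes
  expect_equal(vote_with(15), rep(0L, 4))  # exact tie is a no
  expect_equal(vote_with(16), rep(1L, 4))  # minimal strict majority
  # monotone: adding yes votes never flips a decision to no
  decisions <- vapply(0:30, function(k) vote_with(k)[1], integer(1))
  expect_true(all(diff(decisions) >= 0))
})

test_that("agreement profiles match exhaustive hand counts", {
  mk_const <- function(id, yes) {
    structure(list(hospital_id = id, fit = NULL,
                   constant = if (yes) "yes" else "no",
                   features = strokepathsim:::decision_features,
                   training_size = 100, seed = 1, num_trees = 100),
              class = "decision_model")
  }
  cohort <- ml_eligible(small_system(n_hospitals = 1, admissions = 100L,
                                     seed = 51)$patients)[1:4, ]
  cohort$thrombolysis <- c(1, 0, 0, 1)
  # three constant voters: 2 yes, 1 no -> every patient has 2/3 agreement
  models <- list(mk_const("A", TRUE), mk_const("B", TRUE),
                 mk_const("C", FALSE))
  ap <- agreement_profile(models, cohort, quorum = 0.8)
  expect_equal(ap$overall, 0)  # 2/3 < 0.8 for all four patients
  ap2 <- agreement_profile(models, cohort, quorum = 2 / 3)
  expect_equal(ap2$overall, 1)
  expect_equal(ap2$among_treated, 1)
  expect_equal(ap2$among_untreated, 1)
  # identical models agree everywhere
  same <- list(mk_const("A", TRUE), mk_const("B", TRUE))
  ap3 <- agreement_profile(same, cohort, quorum = 1)
  expect_equal(unlist(ap3), c(overall = 1, among_treated = 1,
                              among_untreated = 1))
  # two models in perfect disagreement never reach a 0.8 quorum
  ap4 <- agreement_profile(list(mk_const("A", TRUE), mk_const("B", FALSE)),
                           cohort, quorum = 0.8)
  expect_equal(ap4$overall, 0)
  expect_error(agreement_profile(same[1], cohort), "at least 2")
})

test_that("predicted cohort rates track planted hospital willingness", {
  cfg <- synth_config(n_hospitals = 10,
                      admissions_per_year_range = c(480L, 480L),
                      hospital_quality_cor = 0, seed = 61)
  h <- generate_hospitals(cfg)
  # spread the planted intercepts over a wide, evenly spaced range
  h$decision_intercept <- cfg$decision_coefficients[["intercept"]] +
    seq(-1.8, 1.8, length.out = 10)
  pat <- generate_patients(h, cfg)
  hold <- holdout_split(pat, prop = 0.2, seed = 3)
  models <- lapply(h$hospital_id, function(id) {
    train_hospital_model(pat, id, exclude_ids = hold, seed = 3)
  })
  cohort <- build_cohort(pat, 1000, hold, seed = 3)
  bench <- select_benchmark(models, cohort, n_benchmark = 10)
  rates <- bench$cohort_rates
  rho <- cor(rates$cohort_rate,
             h$decision_intercept[match(rates$hospital_id, h$hospital_id)],
             method = "spearman")
  expect_gt(rho, 0.8)
})
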