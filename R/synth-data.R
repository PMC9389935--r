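#' Draw the ground-truth hospital system
#'
#' Each hospital gets an annual admission volume, an onset-known proportion,
#' lognormal stage-time parameters for the three pathway stages and a
#' decision-model intercept.  The intercept is the national mean
#' (`decision_coefficients["intercept"]`) plus a zero-mean normal deviation
#' with scale `hospital_intercept_sd`, which is what produces the roughly
#' five-fold between-hospital variation in realised thrombolysis use under
#' the default configuration.
#'
#' @param config a [synth_config()].
#' @return a tibble with one row per hospital: `hospital_id`,
#'   `admissions_per_year`, `p_onset_known`, `mu_oa`, `sigma_oa`, `mu_as`,
#'   `sigma_as`, `mu_sn`, `sigma_sn`, `decision_intercept`.
#' @export
generate_hospitals <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_hospitals
  set.seed(substream_seed(config$seed, "hospitals"))
  apr <- config$admissions_per_year_range
  pri <- config$stage_time_priors
  draw <- function(rng, m) runif(m, rng[1], rng[2])
  # A latent "organisational quality" axis loads (with weight
  # `hospital_quality_cor`) on scan speed, onset ascertainment and
  # willingness to treat; each trait keeps its stated marginal distribution
  # via a Gaussian copula.
  rho <- config$hospital_quality_cor
  quality <- rnorm(n)
  mix <- function() pnorm(rho * quality + sqrt(1 - rho^2) * rnorm(n))
  as_rng <- pri$arrival_to_scan$mu
  mu_as <- as_rng[1] + (as_rng[2] - as_rng[1]) * (1 - mix())
  p_onset_known <- stats::qbeta(mix(), config$p_onset_known_shape[1],
                                config$p_onset_known_shape[2])
  intercept_dev <- config$hospital_intercept_sd *
    (rho * quality + sqrt(1 - rho^2) * rnorm(n))
  tibble::tibble(
    hospital_id = sprintf("H%03d", seq_len(n)),
    admissions_per_year = as.integer(round(draw(apr, n))),
    p_onset_known = p_onset_known,
    mu_oa = draw(pri$onset_to_arrival$mu, n),
    sigma_oa = draw(pri$onset_to_arrival$sigma, n),
    mu_as = mu_as,
    sigma_as = draw(pri$arrival_to_scan$sigma, n),
    mu_sn = draw(pri$scan_to_needle$mu, n),
    sigma_sn = draw(pri$scan_to_needle$sigma, n),
    decision_intercept = config$decision_coefficients[["intercept"]] +
      intercept_dev
  )
}

#' Ground-truth decision linear predictor
#'
#' Log-odds of the treatment decision given patient features, before the
#' ischaemic gate.  Concave in NIHSS (propensity peaks at
#' `config$severity_peak`), so both very mild and very severe strokes are
#' treated less often, as clinicians do in practice.
#'
#' @param patients data frame with columns `nihss`, `onset_precise`,
#'   `age_80plus`, `anticoagulant`, `prestroke_mrs`, `t_oa`.
#' @param intercept hospital intercept (log-odds).
#' @param config a [synth_config()].
#' @return numeric vector of log-odds.
#' @keywords internal
decision_linear_predictor <- function(patients, intercept, config) {
  cf <- config$decision_coefficients
  sev <- -((patients$nihss - config$severity_peak)^2) / config$severity_scale
  intercept +
    cf[["severity"]] * sev +
    cf[["onset_precise"]] * patients$onset_precise +
    cf[["age_80plus"]] * patients$age_80plus +
    cf[["anticoagulant"]] * patients$anticoagulant +
    cf[["prestroke_mrs"]] * patients$prestroke_mrs +
    cf[["onset_to_arrival_hr"]] * (patients$t_oa / 60)
}

draw_patient_features <- function(n, config) {
  tibble::tibble(
    nihss = pmin(pmax(round(stats::rgamma(n, shape = 1.8, scale = 5)), 0), 42),
    prestroke_mrs = sample(0:5, n, replace = TRUE,
                           prob = c(0.55, 0.15, 0.10, 0.10, 0.06, 0.04)),
    age_80plus = rbinom(n, 1, config$p_age_80plus),
    ischemic = rbinom(n, 1, config$p_ischemic),
    anticoagulant = rbinom(n, 1, 0.15),
    arrival_by_ambulance = rbinom(n, 1, 0.75),
    out_of_hospital_onset = rbinom(n, 1, config$p_out_of_hospital)
  )
}

#' Generate patient-level admissions for a hospital system
#'
#' Simulates every emergency stroke admission for the configured number of
#' years at each hospital, drawing pathway times from the hospital's
#' lognormal stage distributions and the treatment flag from the logistic
#' ground-truth decision model, gated by eligibility: treatment requires an
#' ischaemic stroke with known onset, a scan completed within
#' `eligibility_window` minutes of onset, at least `min_remaining` minutes
#' left at scan, and an onset-to-needle time within `treatment_window`
#' minutes.
#'
#' Times are recorded in whole minutes (minimum 1).  Onset-to-arrival is
#' undefined (missing) when onset is unknown; arrival-to-scan is missing for
#' never-scanned patients; scan-to-needle is recorded only for treated
#' patients.
#'
#' @param hospitals tibble from [generate_hospitals()] (or hand-built rows
#'   with the same columns).
#' @param config a [synth_config()].
#' @return a tibble of patient records, one row per admission, with columns
#'   `hospital_id`, `patient_id`, `onset_known`, `onset_precise`,
#'   `out_of_hospital_onset`, `t_oa`, `t_as`, `t_sn`, `age_80plus`, `nihss`,
#'   `ischemic`, `prestroke_mrs`, `anticoagulant`, `arrival_by_ambulance`,
#'   `thrombolysis`.
#' @export
generate_patients <- function(hospitals, config) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(hospitals) < 1) stop("need at least one hospital", call. = FALSE)

  per_hospital <- lapply(seq_len(nrow(hospitals)), function(i) {
    h <- hospitals[i, ]
    set.seed(substream_seed(config$seed, paste0(h$hospital_id, "/patients")))
    n <- h$admissions_per_year * config$years
    feats <- draw_patient_features(n, config)
    onset_known <- rbinom(n, 1, h$p_onset_known)
    onset_precise <- ifelse(onset_known == 1,
                            rbinom(n, 1, config$p_onset_precise), 0L)
    scanned <- rbinom(n, 1, 1 - config$p_missing_scan)

    t_oa <- pmax(round(rlnorm(n, h$mu_oa, h$sigma_oa)), 1)
    t_as <- pmax(round(rlnorm(n, h$mu_as, h$sigma_as)), 1)
    t_sn <- pmax(round(rlnorm(n, h$mu_sn, h$sigma_sn)), 1)
    t_oa[onset_known == 0] <- NA_real_

    pat <- tibble::tibble(
      hospital_id = h$hospital_id,
      patient_id = sprintf("%s-%06d", h$hospital_id, seq_len(n)),
      onset_known = onset_known,
      onset_precise = onset_precise,
      out_of_hospital_onset = feats$out_of_hospital_onset,
      t_oa = t_oa,
      t_as = ifelse(scanned == 1, t_as, NA_real_),
      t_sn = t_sn, # latent; blanked below for untreated patients
      age_80plus = feats$age_80plus,
      nihss = feats$nihss,
      ischemic = feats$ischemic,
      prestroke_mrs = feats$prestroke_mrs,
      anticoagulant = feats$anticoagulant,
      arrival_by_ambulance = feats$arrival_by_ambulance
    )

    eligible <- pat$onset_known == 1 & !is.na(pat$t_as) &
      (pat$t_oa + pat$t_as) <= config$eligibility_window
    p_treat <- pat$ischemic *
      plogis(decision_linear_predictor(pat, h$decision_intercept, config))
    p_treat[!eligible | is.na(p_treat)] <- 0
    wish <- rbinom(n, 1, p_treat)
    remaining <- config$treatment_window - (pat$t_oa + pat$t_as)
    in_window <- !is.na(remaining) & remaining >= config$min_remaining &
      pat$t_sn <= remaining
    pat$thrombolysis <- as.integer(eligible & wish == 1 & in_window)
    pat$t_sn[pat$thrombolysis == 0] <- NA_real_
    pat
  })
  dplyr::bind_rows(per_hospital)
}

#' Brute-force Monte Carlo oracle for a hospital's thrombolysis use
#'
#' Estimates the expected thrombolysis use (treated fraction of all
#' admissions) for one ground-truth hospital by an explicit per-patient
#' loop: each virtual patient's features, onset-known flag, stage times and
#' decision are drawn one at a time and pushed through the eligibility and
#' window gates scalar-by-scalar.  The loop is deliberately independent of
#' the vectorised generator and simulator code paths so it can serve as an
#' oracle for both.
#'
#' @param h one-row tibble with the [generate_hospitals()] columns.
#' @param config a [synth_config()].
#' @param n_mc number of virtual patients (>= 1).
#' @param seed optional seed for the loop's own stream.
#' @return the estimated proportion treated.
#' @export
ground_truth_rate <- function(h, config, n_mc, seed = NULL) {
  stopifnot(inherits(config, "synth_config"), n_mc >= 1)
  if (nrow(h) != 1) stop("`h` must be a single hospital row", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cf <- config$decision_coefficients
  treated <- 0L
  for (i in seq_len(n_mc)) {
    if (runif(1) >= h$p_onset_known) next        # onset never determined
    if (runif(1) < config$p_missing_scan) next   # never scanned
    t_oa <- max(round(rlnorm(1, h$mu_oa, h$sigma_oa)), 1)
    t_as <- max(round(rlnorm(1, h$mu_as, h$sigma_as)), 1)
    if (t_oa + t_as > config$eligibility_window) next
    nihss <- min(max(round(stats::rgamma(1, shape = 1.8, scale = 5)), 0), 42)
    mrs <- sample(0:5, 1, prob = c(0.55, 0.15, 0.10, 0.10, 0.06, 0.04))
    age80 <- runif(1) < config$p_age_80plus
    if (runif(1) >= config$p_ischemic) next      # non-ischaemic: never treated
    anticoag <- runif(1) < 0.15
    precise <- runif(1) < config$p_onset_precise
    eta <- h$decision_intercept +
      cf[["severity"]] *
        (-((nihss - config$severity_peak)^2) / config$severity_scale) +
      cf[["onset_precise"]] * precise +
      cf[["age_80plus"]] * age80 +
      cf[["anticoagulant"]] * anticoag +
      cf[["prestroke_mrs"]] * mrs +
      cf[["onset_to_arrival_hr"]] * (t_oa / 60)
    if (runif(1) >= plogis(eta)) next            # clinician declines
    remaining <- config$treatment_window - (t_oa + t_as)
    if (remaining < config$min_remaining) next
    t_sn <- max(round(rlnorm(1, h$mu_sn, h$sigma_sn)), 1)
    if (t_sn > remaining) next                   # runs out the licence window
    treated <- treated + 1L
  }
  treated / n_mc
}
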