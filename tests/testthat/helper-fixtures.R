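# Shared fixtures, built in code at test time.

# A small but realistic hospital system under the default generator.
small_system <- function(n_hospitals = 6, admissions = 400L, seed = 11,
                         ...) {
  cfg <- synth_config(n_hospitals = n_hospitals,
                      admissions_per_year_range = c(admissions, admissions),
                      seed = seed, ...)
  hospitals <- generate_hospitals(cfg)
  list(config = cfg, hospitals = hospitals,
       patients = generate_patients(hospitals, cfg))
}

# A single hand-built hospital-truth row.
truth_row <- function(hospital_id = "T01", admissions_per_year = 500L,
                      p_onset_known = 0.7, mu_oa = 4.6, sigma_oa = 0.9,
                      mu_as = 3.3, sigma_as = 0.6, mu_sn = 3.2,
                      sigma_sn = 0.4, decision_intercept = 2) {
  tibble::tibble(hospital_id = hospital_id,
                 admissions_per_year = admissions_per_year,
                 p_onset_known = p_onset_known,
                 mu_oa = mu_oa, sigma_oa = sigma_oa,
                 mu_as = mu_as, sigma_as = sigma_as,
                 mu_sn = mu_sn, sigma_sn = sigma_sn,
                 decision_intercept = decision_intercept)
}

# A hand-built pathway-parameter row for the simulator.
params_row <- function(hospital_id = "P01", N_adm = 500,
                       p_onset_known = 0.6, mu_oa = log(60), sigma_oa = 0,
                       mu_as = log(30), sigma_as = 0, mu_sn = log(30),
                       sigma_sn = 0, p_scan4h_arrival = 1,
                       p_treat_eligible = 0.4, p_age_80plus = 0.4,
                       p_scanned = 1) {
  tibble::tibble(hospital_id = hospital_id, N_adm = N_adm,
                 p_onset_known = p_onset_known,
                 mu_oa = mu_oa, sigma_oa = sigma_oa,
                 mu_as = mu_as, sigma_as = sigma_as,
                 mu_sn = mu_sn, sigma_sn = sigma_sn,
                 p_scan4h_arrival = p_scan4h_arrival,
                 p_treat_eligible = p_treat_eligible,
                 p_age_80plus = p_age_80plus, p_scanned = p_scanned)
}

# Config whose ground-truth decision is a constant probability, so the
# generator model coincides with the pathway model and the two can be
# compared exactly.
constant_decision_config <- function(intercept = 0.4, ...) {
  synth_config(
    p_ischemic = 1, p_missing_scan = 0,
    decision_coefficients = c(intercept = intercept, severity = 0,
                              onset_precise = 0, age_80plus = 0,
                              anticoagulant = 0, prestroke_mrs = 0,
                              onset_to_arrival_hr = 0),
    hospital_intercept_sd = 0, ...
  )
}

# Map a hospital-truth row with a constant decision probability onto the
# simulator's parameter vector.
truth_to_params <- function(h, p_treat) {
  params_row(hospital_id = h$hospital_id, N_adm = h$admissions_per_year,
             p_onset_known = h$p_onset_known,
             mu_oa = h$mu_oa, sigma_oa = h$sigma_oa,
             mu_as = h$mu_as, sigma_as = h$sigma_as,
             mu_sn = h$mu_sn, sigma_sn = h$sigma_sn,
             p_treat_eligible = p_treat)
}

# Observed per-hospital thrombolysis use straight from a patient table.
observed_use <- function(patients) {
  rates <- tapply(patients$thrombolysis, patients$hospital_id, mean)
  tibble::tibble(hospital_id = names(rates),
                 thrombolysis_use = as.numeric(rates))
}
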