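#' Simulation configuration
#'
#' Windows and run length for the Monte Carlo pathway model.  The defaults
#' are: the scan must complete within 240 minutes of a known onset for the
#' patient to be considered (the same window that defines the
#' treat-if-eligible likelihood), treatment must start within 270 minutes of
#' onset (the 4.5-hour licence), and at least 15 minutes must remain at scan
#' completion for the drug to be delivered.  One run pushes
#' `N_adm * years_per_hospital` virtual patients through each hospital.
#'
#' @param years_per_hospital years of virtual admissions per hospital.
#' @param eligibility_window minutes, onset to scan completion.
#' @param treatment_window minutes, maximum onset-to-needle.
#' @param min_remaining minutes that must remain before `treatment_window`
#'   at scan completion.
#' @param seed integer base seed; each (hospital, scenario) pair gets its
#'   own sub-stream so results are independent of run order, and scenarios
#'   reuse the hospital stream so comparisons share patient-level noise.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(years_per_hospital = 100,
                       eligibility_window = 240,
                       treatment_window = 270,
                       min_remaining = 15,
                       seed = 1L) {
  if (eligibility_window < 0 || treatment_window < eligibility_window) {
    stop("need `treatment_window` >= `eligibility_window` >= 0", call. = FALSE)
  }
  if (min_remaining < 0) stop("`min_remaining` must be >= 0", call. = FALSE)
  if (years_per_hospital <= 0) {
    stop("`years_per_hospital` must be positive", call. = FALSE)
  }
  structure(list(
    years_per_hospital = years_per_hospital,
    eligibility_window = eligibility_window,
    treatment_window = treatment_window,
    min_remaining = min_remaining,
    seed = as.integer(seed)
  ), class = "sim_config")
}

validate_params_row <- function(params) {
  if (nrow(params) != 1) stop("`params` must be a single hospital row",
                              call. = FALSE)
  for (p in c("p_onset_known", "p_treat_eligible", "p_scanned")) {
    assert_proportion(params[[p]], p)
  }
  for (s in c("sigma_oa", "sigma_as", "sigma_sn")) {
    if (!is.finite(params[[s]]) || params[[s]] < 0) {
      stop(sprintf("`%s` must be >= 0", s), call. = FALSE)
    }
  }
  if (!is.finite(params$N_adm) || params$N_adm <= 0) {
    stop("`N_adm` must be > 0", call. = FALSE)
  }
  invisible(params)
}

#' Monte Carlo simulation of one hospital's thrombolysis pathway
#'
#' Vectorised virtual-patient simulation.  Each patient is pushed through
#' the pathway gates in order and leaves at the first failure:
#' \enumerate{
#'   \item onset time not determined (probability `1 - p_onset_known`);
#'   \item not scanned, or scan completes later than `eligibility_window`
#'     minutes after onset;
#'   \item clinician declines (probability `1 - p_treat_eligible`);
#'   \item too little time left at scan (`< min_remaining` minutes before
#'     `treatment_window`), or onset-to-needle would exceed
#'     `treatment_window`.
#' }
#' Survivors are treated at onset-to-needle time `t_oa + t_as + t_sn`.
#' Stage times are lognormal with the hospital's fitted `(mu, sigma)`; a
#' zero `sigma` gives fixed times.  All draws happen up front in a fixed
#' order, so two scenarios run from the same seed see the same patient-level
#' noise wherever the affected distributions agree.
#'
#' @param params one-row pathway-parameter table
#'   ([estimate_pathway_params()] output or hand-built).
#' @param config a [sim_config()].
#' @param n_patients optional override of `N_adm * years_per_hospital`.
#' @param scenario label stored in the result (also keys the random
#'   sub-stream together with the hospital id, shared across scenarios).
#' @return an object of class `sim_result`: a list with `hospital_id`,
#'   `n_patients`, `n_treated`, `thrombolysis_use`, `onset_to_needle`
#'   (times of the treated), `scenario` and `gates` (patients leaving at
#'   each exit).
#' @export
simulate_hospital <- function(params, config = sim_config(),
                              n_patients = NULL, scenario = "base") {
  stopifnot(inherits(config, "sim_config"))
  validate_params_row(params)
  n <- n_patients %||% round(params$N_adm * config$years_per_hospital)
  n <- as.integer(n)
  if (n < 1) stop("simulation needs at least one virtual patient",
                  call. = FALSE)
  set.seed(substream_seed(config$seed, paste0(params$hospital_id, "/sim")))

  onset_known <- runif(n) < params$p_onset_known
  scanned <- runif(n) < params$p_scanned
  t_oa <- rlnorm(n, params$mu_oa, params$sigma_oa)
  t_as <- rlnorm(n, params$mu_as, params$sigma_as)
  t_sn <- rlnorm(n, params$mu_sn, params$sigma_sn)
  wish <- runif(n) < params$p_treat_eligible

  onset_to_scan <- t_oa + t_as
  pass1 <- onset_known
  pass2 <- pass1 & scanned & onset_to_scan <= config$eligibility_window
  pass3 <- pass2 & wish
  remaining <- config$treatment_window - onset_to_scan
  pass4 <- pass3 & remaining >= config$min_remaining & t_sn <= remaining

  structure(list(
    hospital_id = params$hospital_id,
    n_patients = n,
    n_treated = sum(pass4),
    thrombolysis_use = mean(pass4),
    onset_to_needle = onset_to_scan[pass4] + t_sn[pass4],
    scenario = scenario,
    gates = c(onset_unknown = sum(!pass1),
              not_scanned_in_time = sum(pass1) - sum(pass2),
              not_treated = sum(pass2) - sum(pass3),
              out_of_window = sum(pass3) - sum(pass4),
              treated = sum(pass4))
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s [%s]: %d/%d treated (%.1f%%), median ONT %.0f min\n",
              x$hospital_id, x$scenario, x$n_treated, x$n_patients,
              100 * x$thrombolysis_use,
              if (x$n_treated) stats::median(x$onset_to_needle) else NA))
  invisible(x)
}

#' Simulate a whole hospital system
#'
#' Runs [simulate_hospital()] for every row of `params`.  Each hospital has
#' its own random sub-stream, so the results do not depend on the order of
#' the rows or on which other hospitals are present.
#'
#' @param params pathway-parameter table, one row per hospital.
#' @param config a [sim_config()].
#' @param scenario label recorded in each result.
#' @return a list of `sim_result`, named by hospital id.
#' @export
simulate_system <- function(params, config = sim_config(),
                            scenario = "base") {
  if (nrow(params) < 1) stop("need at least one hospital", call. = FALSE)
  out <- lapply(seq_len(nrow(params)), function(i) {
    simulate_hospital(params[i, ], config, scenario = scenario)
  })
  names(out) <- params$hospital_id
  out
}

#' Tidy summary of simulation results
#'
#' @param results list of `sim_result` ([simulate_system()] output).
#' @return tibble with `hospital_id`, `scenario`, `n_patients`,
#'   `n_treated`, `thrombolysis_use`, `mean_onset_to_needle`.
#' @export
sim_summary <- function(results) {
  dplyr::bind_rows(lapply(results, function(r) {
    tibble::tibble(
      hospital_id = r$hospital_id,
      scenario = r$scenario,
      n_patients = r$n_patients,
      n_treated = r$n_treated,
      thrombolysis_use = r$thrombolysis_use,
      mean_onset_to_needle = if (r$n_treated) mean(r$onset_to_needle) else NA_real_
    )
  }))
}

#' Signed mean difference between observed and predicted values
#'
#' The validation statistic reported alongside the hospital scatter:
#' `mean(observed - predicted)`, in the units of its inputs (percentage
#' points when uses are given in percent).
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return the signed mean difference.
#' @export
mean_difference <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  mean(observed - predicted)
}

#' Validate simulated thrombolysis use against observed use
#'
#' Simulates the base scenario for every hospital and compares predicted
#' use with the observed use, hospital by hospital: the squared Pearson
#' correlation, the signed mean difference (observed minus predicted) and
#' the mean absolute difference, the latter two in percentage points.
#'
#' @param params pathway-parameter table, one row per hospital.
#' @param observed data frame with `hospital_id` and `thrombolysis_use`
#'   (proportion of all admissions).
#' @param config a [sim_config()].
#' @return a list with `r_squared`, `mean_diff`, `mean_abs_diff` and the
#'   per-hospital comparison tibble.
#' @export
validate_against_observed <- function(params, observed,
                                      config = sim_config()) {
  if (!setequal(params$hospital_id, observed$hospital_id)) {
    stop("`params` and `observed` must cover the same hospitals",
         call. = FALSE)
  }
  sims <- sim_summary(simulate_system(params, config))
  cmp <- dplyr::inner_join(
    sims[, c("hospital_id", "thrombolysis_use")],
    observed[, c("hospital_id", "thrombolysis_use")],
    by = "hospital_id", suffix = c("_predicted", "_observed")
  )
  pred <- 100 * cmp$thrombolysis_use_predicted
  obs <- 100 * cmp$thrombolysis_use_observed
  list(
    r_squared = if (stats::var(obs) > 0 && stats::var(pred) > 0)
      cor(obs, pred)^2 else NA_real_,
    mean_diff = mean_difference(obs, pred),
    mean_abs_diff = mean(abs(obs - pred)),
    comparison = cmp
  )
}
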