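#' Scenario transforms of hospital pathway parameters
#'
#' The "what-if" analysis rests on three independent transforms of the
#' per-hospital parameter vector, applied alone or in combination:
#'
#' * **Speed** ([apply_speed()]): 95% of patients are scanned, with a fixed
#'   15-minute arrival-to-scan time; the remaining 5% are not scanned
#'   within 4 hours of arrival and leave at the scan gate.  Scan-to-needle
#'   is fixed at 15 minutes.  Nothing else changes.
#' * **Onset-known** ([apply_onset_known()]): hospitals below the national
#'   upper quartile of the onset-known proportion are raised to it; those
#'   already above keep their own value.
#' * **Benchmark** ([apply_benchmark()]): the treat-if-eligible likelihood
#'   is replaced by the benchmark majority-vote rate for the hospital's own
#'   patients, which may be higher or lower than the hospital's own.
#'
#' All three are idempotent and commute, so combined scenarios do not
#' depend on the order of application.
#'
#' @param params pathway-parameter table (any number of rows).
#' @return the transformed table.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
apply_speed <- function(params) {
  params$mu_as <- log(15)
  params$sigma_as <- 0
  params$mu_sn <- log(15)
  params$sigma_sn <- 0
  params$p_scanned <- 0.95
  params$p_scan4h_arrival <- 0.95
  params
}

#' @rdname scenarios
#' @param national_uq national upper quartile of `p_onset_known`, from
#'   [national_upper_quartile()].
#' @export
apply_onset_known <- function(params, national_uq) {
  assert_proportion(national_uq, "national_uq")
  params$p_onset_known <- pmax(params$p_onset_known, national_uq)
  params
}

#' @rdname scenarios
#' @param bench_rates either a single proportion or a data frame with
#'   `hospital_id` and `benchmark_rate` ([benchmark_rates_all()] output).
#' @export
apply_benchmark <- function(params, bench_rates) {
  if (is.data.frame(bench_rates)) {
    idx <- match(params$hospital_id, bench_rates$hospital_id)
    if (anyNA(idx)) {
      stop("`bench_rates` is missing hospital(s): ",
           paste(params$hospital_id[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    rate <- bench_rates$benchmark_rate[idx]
  } else {
    rate <- bench_rates
  }
  assert_proportion(rate, "bench_rates")
  params$p_treat_eligible <- rate
  params
}

scenario_names <- c("base", "speed", "onset", "benchmark", "speed+onset",
                    "speed+benchmark", "onset+benchmark", "all")

#' Build the parameter table for a named scenario
#'
#' @param params base pathway-parameter table.
#' @param scenario one of `base`, `speed`, `onset`, `benchmark`,
#'   `speed+onset`, `speed+benchmark`, `onset+benchmark`, `all`.
#' @param national_uq required when the scenario includes `onset`.
#' @param bench_rates required when the scenario includes `benchmark`.
#' @return the transformed parameter table.
#' @export
scenario_params <- function(params, scenario, national_uq = NULL,
                            bench_rates = NULL) {
  scenario <- match.arg(scenario, scenario_names)
  parts <- if (scenario == "base") character(0)
           else if (scenario == "all") c("speed", "onset", "benchmark")
           else strsplit(scenario, "+", fixed = TRUE)[[1]]
  if ("speed" %in% parts) params <- apply_speed(params)
  if ("onset" %in% parts) {
    if (is.null(national_uq)) stop("`national_uq` is required", call. = FALSE)
    params <- apply_onset_known(params, national_uq)
  }
  if ("benchmark" %in% parts) {
    if (is.null(bench_rates)) stop("`bench_rates` is required", call. = FALSE)
    params <- apply_benchmark(params, bench_rates)
  }
  params
}

#' National aggregation of simulated use and benefit
#'
#' Admission-weighted means across hospitals of thrombolysis use (as a
#' proportion of all admissions) and of additional good outcomes per 1000
#' admissions.
#'
#' @param use per-hospital thrombolysis use (proportions).
#' @param benefit per-hospital additional good outcomes per 1000.
#' @param weights annual admissions per hospital (positive, matched).
#' @return a list with `use` and `benefit`.
#' @export
aggregate_national <- function(use, benefit, weights) {
  if (length(use) != length(weights) || length(benefit) != length(weights)) {
    stop("`use`, `benefit` and `weights` must have matching lengths",
         call. = FALSE)
  }
  if (any(weights <= 0)) stop("`weights` must be positive", call. = FALSE)
  list(use = weighted.mean(use, weights),
       benefit = weighted.mean(benefit, weights))
}

#' Arithmetic ceiling on the national thrombolysis rate
#'
#' The product of the proportion of admissions arriving within 4 hours of
#' known onset, the ischaemic fraction, and the fraction of ischaemic
#' arrivals suitable for treatment, expressed as a percentage of all
#' emergency admissions.  With 40% timely arrivals, 85% ischaemic and 60%
#' suitable this is 20.4%, i.e. a potential target of 20% once rounded to
#' the nearest whole percent.
#'
#' @param p_within4h proportion arriving within 4 h of known onset.
#' @param p_ischemic proportion of strokes that are ischaemic.
#' @param p_suitable proportion of timely ischaemic arrivals suitable for
#'   treatment.
#' @return the ceiling rate in percent (unrounded).
#' @export
ceiling_rate <- function(p_within4h, p_ischemic, p_suitable) {
  assert_proportion(p_within4h, "p_within4h")
  assert_proportion(p_ischemic, "p_ischemic")
  assert_proportion(p_suitable, "p_suitable")
  100 * p_within4h * p_ischemic * p_suitable
}

#' Run the scenario engine across a hospital system
#'
#' Simulates the base scenario and any requested what-if scenarios for
#' every hospital, attaches the expected clinical benefit, and returns a
#' tidy per-hospital table plus admission-weighted national summaries.
#'
#' @param params base pathway-parameter table.
#' @param scenarios character vector of scenario names (must include
#'   `"base"` implicitly; it is always run).
#' @param config a [sim_config()].
#' @param national_uq,bench_rates passed to [scenario_params()] as needed.
#' @param outcome an [outcome_params()] object.
#' @return a list with `hospital` (per-hospital tibble: `hospital_id`,
#'   `scenario`, `thrombolysis_use`, `benefit_per_1000`) and `national`
#'   (per-scenario tibble of weighted `use` and `benefit`).
#' @export
run_scenarios <- function(params, scenarios = c("speed", "onset",
                                                "benchmark", "all"),
                          config = sim_config(), national_uq = NULL,
                          bench_rates = NULL,
                          outcome = outcome_params()) {
  scenarios <- union("base", scenarios)
  per_scenario <- lapply(scenarios, function(sc) {
    sp <- scenario_params(params, sc, national_uq, bench_rates)
    results <- simulate_system(sp, config, scenario = sc)
    benefit <- vapply(seq_along(results), function(i) {
      additional_good_outcomes(results[[i]], sp$p_age_80plus[i], outcome)
    }, 0)
    out <- sim_summary(results)
    out$benefit_per_1000 <- benefit
    out
  })
  hospital <- dplyr::bind_rows(per_scenario)
  national <- dplyr::bind_rows(lapply(split(hospital, hospital$scenario),
    function(d) {
      w <- params$N_adm[match(d$hospital_id, params$hospital_id)]
      agg <- aggregate_national(d$thrombolysis_use, d$benefit_per_1000, w)
      tibble::tibble(scenario = d$scenario[1], use = agg$use,
                     benefit = agg$benefit)
    }))
  national <- national[match(intersect(c("base", "speed", "onset",
                                         "benchmark", "speed+onset",
                                         "speed+benchmark",
                                         "onset+benchmark", "all"),
                                       national$scenario),
                             national$scenario), ]
  list(hospital = hospital, national = national)
}
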