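#' Fit a lognormal distribution to stage times
#'
#' Method-of-moments on the log scale: `mu` is the mean of log-times and
#' `sigma` the *population* standard deviation of log-times (divisor `n`,
#' not `n - 1`), so that e.g. samples `exp(1), exp(3)` give exactly
#' `(mu = 2, sigma = 1)`.  Non-positive times are clamped to 1 minute before
#' the log transform.
#'
#' @param samples numeric vector of times in minutes; `NA`s are dropped.
#' @param label optional label (hospital/stage) used in error messages.
#' @return named numeric `c(mu, sigma)` in log-minutes.
#' @export
fit_lognormal <- function(samples, label = NULL) {
  x <- samples[is.finite(samples)]
  x[x <= 0] <- 1
  if (length(x) < 2) {
    stop(sprintf("need >= 2 usable time samples%s (got %d)",
                 if (is.null(label)) "" else paste0(" for ", label),
                 length(x)), call. = FALSE)
  }
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  c(mu = mu, sigma = sigma)
}

#' Estimate a hospital's pathway parameters from patient-level data
#'
#' Derives the parameter vector that drives [simulate_hospital()] from one
#' hospital's admissions, restricted to out-of-hospital-onset strokes:
#' the onset-known proportion, lognormal fits to the three stage times
#' (over records where the stage time is defined), the proportion scanned
#' within 4 hours of arrival, and the likelihood to treat among patients
#' scanned within `eligibility_window` minutes of known onset.
#'
#' @param patients patient table (schema of [generate_patients()]).
#' @param hospital_id hospital to estimate.
#' @param eligibility_window minutes from onset within which the scan must
#'   complete to enter the treatment-likelihood denominator.
#' @param years years of data in `patients`, used to convert the row count
#'   to admissions per year.
#' @return a one-row tibble of pathway parameters with columns:
#'   `hospital_id`, `N_adm`, `p_onset_known`, `mu_oa`, `sigma_oa`, `mu_as`,
#'   `sigma_as`, `mu_sn`, `sigma_sn`, `p_scan4h_arrival`,
#'   `p_treat_eligible`, `p_age_80plus`, `p_scanned`.
#' @export
estimate_pathway_params <- function(patients, hospital_id,
                                    eligibility_window = 240, years = 3) {
  pts <- patients[patients$hospital_id == hospital_id &
                    patients$out_of_hospital_onset == 1, ]
  if (nrow(pts) == 0) {
    stop(sprintf("hospital '%s' not present in the patient table",
                 hospital_id), call. = FALSE)
  }
  oa <- fit_lognormal(pts$t_oa[pts$onset_known == 1],
                      paste0(hospital_id, "/onset_to_arrival"))
  as_ <- fit_lognormal(pts$t_as, paste0(hospital_id, "/arrival_to_scan"))
  sn <- fit_lognormal(pts$t_sn[pts$thrombolysis == 1],
                      paste0(hospital_id, "/scan_to_needle"))
  eligible <- pts$onset_known == 1 & !is.na(pts$t_as) &
    (pts$t_oa + pts$t_as) <= eligibility_window
  n_eligible <- sum(eligible, na.rm = TRUE)
  if (n_eligible == 0) {
    warning(sprintf("hospital '%s': no patients scanned within %g min of known onset; p_treat_eligible set to 0",
                    hospital_id, eligibility_window), call. = FALSE)
    p_treat <- 0
  } else {
    p_treat <- sum(pts$thrombolysis[eligible]) / n_eligible
  }
  tibble::tibble(
    hospital_id = hospital_id,
    N_adm = nrow(pts) / years,
    p_onset_known = mean(pts$onset_known),
    mu_oa = oa[["mu"]], sigma_oa = oa[["sigma"]],
    mu_as = as_[["mu"]], sigma_as = as_[["sigma"]],
    mu_sn = sn[["mu"]], sigma_sn = sn[["sigma"]],
    p_scan4h_arrival = mean(!is.na(pts$t_as) & pts$t_as <= 240),
    p_treat_eligible = p_treat,
    p_age_80plus = mean(pts$age_80plus),
    p_scanned = 1
  )
}

#' Estimate pathway parameters for every hospital in a patient table
#'
#' @inheritParams estimate_pathway_params
#' @return a tibble with one `hospital_pathway_params` row per hospital,
#'   ordered by hospital id.
#' @export
fit_pathway_params <- function(patients, eligibility_window = 240,
                               years = 3) {
  ids <- sort(unique(patients$hospital_id))
  dplyr::bind_rows(lapply(ids, function(id) {
    estimate_pathway_params(patients, id, eligibility_window, years)
  }))
}

#' National upper quartile of the onset-known proportion
#'
#' The unweighted 75th percentile of `p_onset_known` across hospitals
#' (every hospital counts equally, regardless of size), using the standard
#' linear-interpolation quantile definition (`stats::quantile()` type 7),
#' so e.g. values `0.2, 0.4, 0.6, 0.8` give 0.65.
#'
#' @param params pathway-parameter table ([fit_pathway_params()] output).
#' @return the upper-quartile proportion.
#' @export
national_upper_quartile <- function(params) {
  if (nrow(params) < 4) {
    stop("need at least 4 hospitals to take a national upper quartile",
         call. = FALSE)
  }
  unname(quantile(params$p_onset_known, 0.75, type = 7))
}
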