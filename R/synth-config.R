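#' Configuration for the synthetic stroke-audit generator
#'
#' Builds the configuration object that drives [generate_hospitals()] and
#' [generate_patients()].  The defaults emulate the statistical structure of
#' national stroke-audit (SSNAP-like) emergency admissions data: roughly 130
#' acute hospitals, three years of admissions each, about two thirds of
#' patients with a determined onset time, marked between-hospital variation
#' in pathway speed, and an approximately five-fold spread in willingness to
#' treat around a national thrombolysis use of 11-12% of all admissions.
#'
#' Stage times are lognormal.  The ground-truth treatment decision is
#' logistic in patient features (concave in NIHSS, so very mild and very
#' severe strokes are treated less) plus a hospital-level intercept; a
#' patient can only be treated when the stroke is ischaemic, onset time is
#' known, the scan completes within `eligibility_window` minutes of onset,
#' and treatment can start within `treatment_window` minutes of onset.
#'
#' @param n_hospitals number of hospitals in the system.
#' @param years years of admissions generated per hospital.
#' @param admissions_per_year_range integer `(min, max)`; each hospital's
#'   annual admission count is drawn uniformly from this range.
#' @param p_onset_known_shape `(alpha, beta)` of the Beta distribution from
#'   which each hospital's onset-known proportion is drawn.  The default
#'   `c(20, 10)` has mean 2/3.
#' @param stage_time_priors per-stage uniform prior ranges for the lognormal
#'   location (`mu`, log-minutes) and scale (`sigma`): a list with elements
#'   `onset_to_arrival`, `arrival_to_scan`, `scan_to_needle`, each a list of
#'   `mu = c(lo, hi)` and `sigma = c(lo, hi)`.
#' @param p_age_80plus proportion of patients aged 80 or over.
#' @param p_ischemic proportion of strokes that are ischaemic.
#' @param p_missing_scan proportion of admissions never scanned (recorded as
#'   a missing arrival-to-scan time, never zero).
#' @param p_out_of_hospital proportion of strokes with out-of-hospital onset.
#' @param p_onset_precise probability that a known onset time is precise
#'   (rather than a best estimate).
#' @param decision_coefficients named log-odds weights of the ground-truth
#'   decision model: `intercept` (national mean), `severity` (weight on the
#'   concave NIHSS term), `onset_precise`, `age_80plus`, `anticoagulant`,
#'   `prestroke_mrs`, `onset_to_arrival_hr` (per hour of onset-to-arrival).
#' @param severity_peak NIHSS at which the ground-truth treatment propensity
#'   peaks.
#' @param severity_scale divisor of the squared NIHSS distance in the
#'   concave severity term.
#' @param hospital_intercept_sd standard deviation (log-odds) of hospital
#'   intercepts around the national mean; drives the between-hospital
#'   variation in thrombolysis use.
#' @param hospital_quality_cor loading of a latent "organisational
#'   quality" axis on three hospital traits: arrival-to-scan speed, the
#'   onset-known proportion and the decision intercept.  Well-organised
#'   stroke units tend to be faster, better at establishing onset times
#'   and more willing to treat; the upper tail of observed hospital
#'   thrombolysis rates is only reachable when these coincide.  Zero makes
#'   the traits independent.
#' @param eligibility_window minutes from onset within which the scan must
#'   complete for the patient to be considered for treatment.
#' @param treatment_window maximum onset-to-needle time in minutes.
#' @param min_remaining minimum minutes that must remain before
#'   `treatment_window` at scan completion for treatment to be delivered.
#' @param seed integer seed; all generation is deterministic given the
#'   configuration.
#'
#' @return an object of class `synth_config` (a named list).
#' @export
#' @examples
#' cfg <- synth_config(n_hospitals = 5, seed = 42)
#' hospitals <- generate_hospitals(cfg)
synth_config <- function(n_hospitals = 132,
                         years = 3,
                         admissions_per_year_range = c(350L, 900L),
                         p_onset_known_shape = c(20, 10),
                         stage_time_priors = list(
                           onset_to_arrival = list(mu = c(5.05, 5.50),
                                                   sigma = c(0.90, 1.20)),
                           arrival_to_scan  = list(mu = c(2.90, 4.10),
                                                   sigma = c(0.60, 1.00)),
                           scan_to_needle   = list(mu = c(3.10, 3.60),
                                                   sigma = c(0.40, 0.60))
                         ),
                         p_age_80plus = 0.40,
                         p_ischemic = 0.85,
                         p_missing_scan = 0.02,
                         p_out_of_hospital = 0.95,
                         p_onset_precise = 0.60,
                         decision_coefficients = c(
                           intercept = 4.50,
                           severity = 3.00,
                           onset_precise = 1.80,
                           age_80plus = -1.00,
                           anticoagulant = -4.20,
                           prestroke_mrs = -1.20,
                           onset_to_arrival_hr = -0.70
                         ),
                         severity_peak = 12,
                         severity_scale = 50,
                         hospital_intercept_sd = 1.45,
                         hospital_quality_cor = 0.55,
                         eligibility_window = 240,
                         treatment_window = 270,
                         min_remaining = 15,
                         seed = 1L) {
  if (!is.numeric(n_hospitals) || length(n_hospitals) != 1 ||
      is.na(n_hospitals) || n_hospitals < 1) {
    stop("`n_hospitals` must be a single integer >= 1", call. = FALSE)
  }
  if (years < 1) stop("`years` must be >= 1", call. = FALSE)
  assert_range(admissions_per_year_range, "admissions_per_year_range")
  if (admissions_per_year_range[1] < 1) {
    stop("`admissions_per_year_range` must be positive", call. = FALSE)
  }
  if (length(p_onset_known_shape) != 2 || any(p_onset_known_shape <= 0)) {
    stop("`p_onset_known_shape` must be two positive Beta shapes",
         call. = FALSE)
  }
  for (stage in c("onset_to_arrival", "arrival_to_scan", "scan_to_needle")) {
    pri <- stage_time_priors[[stage]]
    if (is.null(pri)) {
      stop(sprintf("`stage_time_priors` is missing stage '%s'", stage),
           call. = FALSE)
    }
    assert_range(pri$mu, paste0("stage_time_priors$", stage, "$mu"))
    assert_range(pri$sigma, paste0("stage_time_priors$", stage, "$sigma"))
    if (pri$sigma[1] < 0) {
      stop(sprintf("`stage_time_priors$%s$sigma` must be >= 0", stage),
           call. = FALSE)
    }
  }
  assert_proportion(p_age_80plus, "p_age_80plus")
  assert_proportion(p_ischemic, "p_ischemic")
  assert_proportion(p_missing_scan, "p_missing_scan")
  assert_proportion(p_out_of_hospital, "p_out_of_hospital")
  assert_proportion(p_onset_precise, "p_onset_precise")
  needed <- c("intercept", "severity", "onset_precise", "age_80plus",
              "anticoagulant", "prestroke_mrs", "onset_to_arrival_hr")
  if (!all(needed %in% names(decision_coefficients))) {
    stop("`decision_coefficients` must name: ",
         paste(setdiff(needed, names(decision_coefficients)), collapse = ", "),
         call. = FALSE)
  }
  if (hospital_intercept_sd < 0) {
    stop("`hospital_intercept_sd` must be >= 0", call. = FALSE)
  }
  if (abs(hospital_quality_cor) > 1) {
    stop("`hospital_quality_cor` must be in [-1, 1]", call. = FALSE)
  }
  if (eligibility_window < 0 || treatment_window < eligibility_window) {
    stop("need `treatment_window` >= `eligibility_window` >= 0", call. = FALSE)
  }
  if (min_remaining < 0) stop("`min_remaining` must be >= 0", call. = FALSE)

  structure(list(
    n_hospitals = as.integer(n_hospitals),
    years = as.integer(years),
    admissions_per_year_range = as.integer(admissions_per_year_range),
    p_onset_known_shape = as.numeric(p_onset_known_shape),
    stage_time_priors = stage_time_priors,
    p_age_80plus = p_age_80plus,
    p_ischemic = p_ischemic,
    p_missing_scan = p_missing_scan,
    p_out_of_hospital = p_out_of_hospital,
    p_onset_precise = p_onset_precise,
    decision_coefficients = decision_coefficients[needed],
    severity_peak = severity_peak,
    severity_scale = severity_scale,
    hospital_intercept_sd = hospital_intercept_sd,
    hospital_quality_cor = hospital_quality_cor,
    eligibility_window = eligibility_window,
    treatment_window = treatment_window,
    min_remaining = min_remaining,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic stroke-audit configuration\n")
  cat(sprintf("  %d hospitals x %d years, %d-%d admissions/year\n",
              x$n_hospitals, x$years,
              x$admissions_per_year_range[1], x$admissions_per_year_range[2]))
  cat(sprintf("  onset known ~ Beta(%g, %g); ischaemic %.0f%%; age 80+ %.0f%%\n",
              x$p_onset_known_shape[1], x$p_onset_known_shape[2],
              100 * x$p_ischemic, 100 * x$p_age_80plus))
  cat(sprintf("  windows: scan by %g min of onset, needle by %g min\n",
              x$eligibility_window, x$treatment_window))
  cat(sprintf("  hospital intercept sd %.2f (log-odds); seed %d\n",
              x$hospital_intercept_sd, x$seed))
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' The YAML file holds exactly the fields of [synth_config()]; missing
#' fields fall back to the defaults.
#'
#' @param path file path.
#' @param config a `synth_config` object (for writing).
#' @return `read_synth_config()` returns a `synth_config`;
#'   `write_synth_config()` returns `path` invisibly.
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(synth_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown configuration field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$decision_coefficients)) {
    raw$decision_coefficients <- unlist(raw$decision_coefficients)
  }
  do.call(synth_config, raw)
}

#' @rdname read_synth_config
#' @export
write_synth_config <- function(config, path) {
  stopifnot(inherits(config, "synth_config"))
  out <- unclass(config)
  out$decision_coefficients <- as.list(out$decision_coefficients)
  yaml::write_yaml(out, path)
  invisible(path)
}
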