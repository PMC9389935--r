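#' Outcome-model parameters
#'
#' The chance of an excellent recovery (modified Rankin Scale 0-1 at 3-6
#' months) is modelled per age group (under 80, 80 and over) by three
#' numbers: `p0`, the probability without thrombolysis; `p_t0`, the
#' probability if treated immediately at onset; and `t_ne`, the time of no
#' effect in minutes, at which the treated benefit has decayed to baseline.
#' Between 0 and `t_ne` the log-odds of a good outcome decline linearly
#' with onset-to-needle time; beyond `t_ne` treatment confers no modelled
#' benefit (and no modelled harm).
#'
#' The shipped defaults are illustrative placeholder values chosen to be
#' clinically plausible (benefit decaying to nothing at 6.3 hours, smaller
#' absolute probabilities in the older group); studies applying the model
#' should supply their own coefficients, e.g. via [read_outcome_params()].
#'
#' @param under_80,over_80 lists with elements `p0`, `p_t0`, `t_ne`.
#' @return an object of class `outcome_params`.
#' @export
outcome_params <- function(under_80 = list(p0 = 0.20, p_t0 = 0.33,
                                           t_ne = 378),
                           over_80 = list(p0 = 0.07, p_t0 = 0.14,
                                          t_ne = 378)) {
  for (grp in list(under_80, over_80)) {
    if (!all(c("p0", "p_t0", "t_ne") %in% names(grp))) {
      stop("each age group needs `p0`, `p_t0` and `t_ne`", call. = FALSE)
    }
    if (!(grp$p0 >= 0 && grp$p0 <= grp$p_t0 && grp$p_t0 <= 1)) {
      stop("need 0 <= p0 <= p_t0 <= 1 in each age group", call. = FALSE)
    }
    if (grp$t_ne <= 0) stop("`t_ne` must be > 0", call. = FALSE)
  }
  structure(list(under_80 = under_80, over_80 = over_80),
            class = "outcome_params")
}

#' Read outcome-model parameters from a YAML file
#'
#' Expects an `outcome_model:` block with `under_80:` and `over_80:`
#' sub-blocks each holding `p0`, `p_t0`, `t_ne`.
#'
#' @param path YAML file path.
#' @return an `outcome_params` object.
#' @export
read_outcome_params <- function(path) {
  raw <- yaml::read_yaml(path)
  blk <- raw$outcome_model %||% raw
  outcome_params(under_80 = blk$under_80, over_80 = blk$over_80)
}

#' Probability of a good outcome (mRS 0-1)
#'
#' Untreated patients get the age group's baseline `p0`.  Treated patients
#' get a probability whose log-odds are interpolated linearly in time
#' between `qlogis(p_t0)` at onset-to-needle time 0 and `qlogis(p0)` at
#' `t_ne`; treatment later than `t_ne` reverts to `p0` (no harm is
#' modelled).  Vectorised over patients.
#'
#' @param treated logical/0-1 vector.
#' @param t_ont onset-to-needle times in minutes (ignored where untreated).
#' @param age_80plus logical/0-1 vector.
#' @param params an [outcome_params()] object.
#' @return vector of probabilities.
#' @export
p_good <- function(treated, t_ont, age_80plus, params = outcome_params()) {
  stopifnot(inherits(params, "outcome_params"))
  n <- max(length(treated), length(t_ont), length(age_80plus))
  treated <- rep_len(as.logical(treated), n)
  t_ont <- rep_len(as.numeric(t_ont), n)
  age_80plus <- rep_len(as.logical(age_80plus), n)
  if (any(treated & (!is.finite(t_ont) | t_ont < 0))) {
    stop("treated patients need a finite onset-to-needle time >= 0",
         call. = FALSE)
  }
  p0 <- ifelse(age_80plus, params$over_80$p0, params$under_80$p0)
  pt0 <- ifelse(age_80plus, params$over_80$p_t0, params$under_80$p_t0)
  tne <- ifelse(age_80plus, params$over_80$t_ne, params$under_80$t_ne)
  frac <- pmin(ifelse(treated, t_ont, 0) / tne, 1)
  lo <- qlogis(pt0) + (qlogis(p0) - qlogis(pt0)) * frac
  ifelse(treated, plogis(lo), p0)
}

#' Additional good outcomes per 1000 admissions
#'
#' Expected excess of mRS 0-1 outcomes attributable to thrombolysis in a
#' simulated hospital: for each treated patient the benefit over baseline
#' `p_good(t) - p0`, averaged over the age mix, summed and scaled per 1000
#' admissions.  The aggregate is computed in expectation (probabilities are
#' summed, outcomes are not sampled), so it carries no outcome-level Monte
#' Carlo noise.
#'
#' @param result a `sim_result` from [simulate_hospital()].
#' @param p_age_80plus the hospital's proportion of patients aged 80+.
#' @param params an [outcome_params()] object.
#' @return additional good outcomes per 1000 admissions (>= 0).
#' @export
additional_good_outcomes <- function(result, p_age_80plus,
                                     params = outcome_params()) {
  stopifnot(inherits(result, "sim_result"))
  assert_proportion(p_age_80plus, "p_age_80plus")
  t <- result$onset_to_needle
  if (length(t) == 0) return(0)
  benefit_young <- p_good(TRUE, t, FALSE, params) - params$under_80$p0
  benefit_old <- p_good(TRUE, t, TRUE, params) - params$over_80$p0
  per_patient <- (1 - p_age_80plus) * benefit_young +
    p_age_80plus * benefit_old
  1000 * sum(per_patient) / result$n_patients
}
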