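#' Write the scenario report: tables, validation statistics and figures
#'
#' Produces the standard output bundle of a scenario run under `out_dir`:
#'
#' * `hospital_results.csv` — one row per hospital x scenario with
#'   thrombolysis use (% of all admissions, 1 decimal place) and additional
#'   good outcomes per 1000 admissions;
#' * `national_summary.csv` — admission-weighted national use and benefit
#'   per scenario, identical to [aggregate_national()] on the same rows;
#' * `validation.csv` — R-squared, signed mean difference and mean absolute
#'   difference (percentage points) between simulated base-scenario use and
#'   observed use;
#' * `validation_scatter.png` — observed vs predicted use with a 1:1 line;
#' * `scenario_use.png` / `scenario_benefit.png` — national bars per
#'   scenario;
#' * `hospital_histograms.png` — before/after ("base" vs "all")
#'   distributions of use and benefit across hospitals.
#'
#' Rerunning with identical inputs rewrites identical CSVs.
#'
#' @param scenario_run output of [run_scenarios()] (must include the base
#'   scenario and at least one other).
#' @param observed data frame with `hospital_id` and `thrombolysis_use`
#'   (proportion of all admissions) for validation.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_report <- function(scenario_run, observed, out_dir) {
  hospital <- scenario_run$hospital
  national <- scenario_run$national
  if (!"base" %in% hospital$scenario) {
    stop("the base scenario is missing from the run", call. = FALSE)
  }
  if (length(unique(hospital$scenario)) < 2) {
    stop("need the base scenario plus at least one what-if scenario",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  hosp_out <- tibble::tibble(
    hospital_id = hospital$hospital_id,
    scenario = hospital$scenario,
    thrombolysis_use_pct = round(100 * hospital$thrombolysis_use, 1),
    benefit_per_1000 = round(hospital$benefit_per_1000, 2)
  )
  p <- file.path(out_dir, "hospital_results.csv")
  readr::write_csv(hosp_out, p); paths <- c(paths, p)

  nat_out <- tibble::tibble(
    scenario = national$scenario,
    thrombolysis_use_pct = round(100 * national$use, 1),
    benefit_per_1000 = round(national$benefit, 2)
  )
  p <- file.path(out_dir, "national_summary.csv")
  readr::write_csv(nat_out, p); paths <- c(paths, p)

  base <- hospital[hospital$scenario == "base", ]
  val_cmp <- dplyr::inner_join(
    base[, c("hospital_id", "thrombolysis_use")],
    observed[, c("hospital_id", "thrombolysis_use")],
    by = "hospital_id", suffix = c("_predicted", "_observed")
  )
  pred <- 100 * val_cmp$thrombolysis_use_predicted
  obs <- 100 * val_cmp$thrombolysis_use_observed
  val <- tibble::tibble(
    r_squared = cor(obs, pred)^2,
    mean_diff_pct_points = mean_difference(obs, pred),
    mean_abs_diff_pct_points = mean(abs(obs - pred))
  )
  p <- file.path(out_dir, "validation.csv")
  readr::write_csv(val, p); paths <- c(paths, p)

  gg <- ggplot2::ggplot(
    tibble::tibble(observed = obs, predicted = pred),
    ggplot2::aes(x = observed, y = predicted)) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Observed thrombolysis use (%)",
                  y = "Predicted thrombolysis use (%)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  p <- file.path(out_dir, "validation_scatter.png")
  ggplot2::ggsave(p, gg, width = 5, height = 5, dpi = 150); paths <- c(paths, p)

  nat_long <- nat_out
  nat_long$scenario <- factor(nat_long$scenario,
                              levels = unique(nat_long$scenario))
  gg <- ggplot2::ggplot(nat_long,
                        ggplot2::aes(x = scenario,
                                     y = thrombolysis_use_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Thrombolysis use (% of admissions)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  p <- file.path(out_dir, "scenario_use.png")
  ggplot2::ggsave(p, gg, width = 6, height = 4, dpi = 150); paths <- c(paths, p)

  gg <- ggplot2::ggplot(nat_long,
                        ggplot2::aes(x = scenario, y = benefit_per_1000)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL,
                  y = "Additional good outcomes per 1000 admissions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  p <- file.path(out_dir, "scenario_benefit.png")
  ggplot2::ggsave(p, gg, width = 6, height = 4, dpi = 150); paths <- c(paths, p)

  final <- if ("all" %in% hospital$scenario) "all"
           else setdiff(unique(hospital$scenario), "base")[1]
  hh <- hospital[hospital$scenario %in% c("base", final), ]
  hh_long <- rbind(
    tibble::tibble(scenario = hh$scenario,
                   metric = "Thrombolysis use (%)",
                   value = 100 * hh$thrombolysis_use),
    tibble::tibble(scenario = hh$scenario,
                   metric = "Benefit per 1000",
                   value = hh$benefit_per_1000)
  )
  gg <- ggplot2::ggplot(hh_long,
                        ggplot2::aes(x = value, fill = scenario)) +
    ggplot2::geom_histogram(alpha = 0.5, position = "identity", bins = 20) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "Hospitals") +
    ggplot2::theme_minimal()
  p <- file.path(out_dir, "hospital_histograms.png")
  ggplot2::ggsave(p, gg, width = 8, height = 4, dpi = 150); paths <- c(paths, p)

  invisible(paths)
}
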