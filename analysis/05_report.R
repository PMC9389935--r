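#!/usr/bin/env Rscript
# Step 5: validation and reporting.  Compares simulated base-scenario use
# with the "observed" use in the generated records (the synthetic stand-in
# for audit data), then writes the report bundle: per-hospital and
# national CSVs, validation statistics and figures.

library(strokepathsim)

patients <- read_patients("results/patients.csv")
params <- readr::read_csv("results/pathway_params.csv",
                          show_col_types = FALSE)
hospital <- readr::read_csv("results/scenario_hospital.csv",
                            show_col_types = FALSE)
national <- readr::read_csv("results/scenario_national.csv",
                            show_col_types = FALSE)

rates <- tapply(patients$thrombolysis, patients$hospital_id, mean)
observed <- tibble::tibble(hospital_id = names(rates),
                           thrombolysis_use = as.numeric(rates))

v <- validate_against_observed(params, observed,
                               sim_config(years_per_hospital = 100,
                                          seed = 77))
cat(sprintf("validation against observed use: R-squared %.3f, mean difference %.2f, mean absolute difference %.2f percentage points\n",
            v$r_squared, v$mean_diff, v$mean_abs_diff))

paths <- write_report(list(hospital = hospital, national = national),
                      observed, "results/report")
cat("report written:\n")
cat(paste0("  ", paths, collapse = "\n"), "\n")

base <- national[national$scenario == "base", ]
all3 <- national[national$scenario == "all", ]
cat(sprintf("combined changes: use %.1f%% -> %.1f%%, benefit %.1f -> %.1f per 1000\n",
            100 * base$use, 100 * all3$use, base$benefit, all3$benefit))
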