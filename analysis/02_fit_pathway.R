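#!/usr/bin/env Rscript
# Step 2: estimate each hospital's pathway parameters from the patient
# records (out-of-hospital-onset strokes only): onset-known proportion,
# lognormal stage-time fits, and the likelihood to treat among patients
# scanned within 4 hours of known onset.

library(strokepathsim)

patients <- read_patients("results/patients.csv")
cfg <- read_synth_config("results/synth_config.yaml")

params <- fit_pathway_params(patients, eligibility_window =
                               cfg$eligibility_window, years = cfg$years)
readr::write_csv(params, "results/pathway_params.csv")

uq <- national_upper_quartile(params)
cat(sprintf("fitted pathway parameters for %d hospitals\n", nrow(params)))
cat(sprintf("onset-known proportion: median %.2f, national upper quartile %.2f\n",
            median(params$p_onset_known), uq))
cat(sprintf("median stage medians (min): onset-to-arrival %.0f, arrival-to-scan %.0f, scan-to-needle %.0f\n",
            median(exp(params$mu_oa)), median(exp(params$mu_as)),
            median(exp(params$mu_sn))))
cat(sprintf("likelihood to treat if scanned in time: %.2f to %.2f (median %.2f)\n",
            min(params$p_treat_eligible), max(params$p_treat_eligible),
            median(params$p_treat_eligible)))
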