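#!/usr/bin/env Rscript
# Step 1: generate the synthetic national stroke-audit extract.
#
# Emulates ~132 acute hospitals x 3 years of emergency stroke admissions
# with between-hospital variation in pathway speed, onset-time
# ascertainment and willingness to treat.  Writes the patient-level CSV,
# the generator configuration and the ground-truth hospital table (kept for
# parameter-recovery checks; a real audit has no such table).

library(strokepathsim)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- synth_config(seed = 20160101)
hospitals <- generate_hospitals(cfg)
patients <- generate_patients(hospitals, cfg)

write_synth_config(cfg, file.path(out_dir, "synth_config.yaml"))
readr::write_csv(hospitals, file.path(out_dir, "hospital_truth.csv"))
write_patients(patients, file.path(out_dir, "patients.csv"))

rates <- tapply(patients$thrombolysis, patients$hospital_id, mean)
cat(sprintf("generated %d admissions across %d hospitals (%d years)\n",
            nrow(patients), nrow(hospitals), cfg$years))
cat(sprintf("pooled thrombolysis use: %.1f%% of all admissions\n",
            100 * mean(patients$thrombolysis)))
cat(sprintf("hospital-level use: %.1f%% to %.1f%% (%.1f-fold variation)\n",
            100 * min(rates), 100 * max(rates), max(rates) / min(rates)))
cat(sprintf("arriving within 4 h of known onset: %.1f%%\n",
            100 * mean(patients$onset_known == 1 & !is.na(patients$t_oa) &
                         patients$t_oa <= 240)))
cat(sprintf("onset time determined: %.1f%%\n",
            100 * mean(patients$onset_known)))
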