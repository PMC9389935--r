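#!/usr/bin/env Rscript
# Step 3: learn each hospital's thrombolysis decision-making and build the
# benchmark.  A random forest per hospital is trained on its patients
# arriving within 4 hours of known onset (with a fixed holdout excluded);
# a shared 10k held-out cohort is scored by every model; the 30 hospitals
# with the highest predicted cohort use form the benchmark whose majority
# vote defines the benchmark treatment rate for each hospital's own
# patients.

library(strokepathsim)

patients <- read_patients("results/patients.csv")

hold <- holdout_split(patients, prop = 0.2, seed = 1001)
eligible <- ml_eligible(patients)
sizes <- table(eligible$hospital_id[!eligible$patient_id %in% hold])
trainable <- names(sizes)[sizes >= 25]
cat(sprintf("%d of %d hospitals have >= 25 eligible training patients\n",
            length(trainable), length(unique(patients$hospital_id))))

models <- lapply(trainable, function(id) {
  train_hospital_model(patients, id, exclude_ids = hold, seed = 1001)
})

# cross-validated metrics for a systematic sample of ten hospitals
sample_ids <- trainable[round(seq(1, length(trainable), length.out = 10))]
metrics <- dplyr::bind_rows(lapply(sample_ids, function(id) {
  m <- models[[match(id, trainable)]]
  ev <- evaluate_model(m, patients, k = 5)
  tibble::tibble(hospital_id = id, n_eligible = ev$n,
                 accuracy = ev$accuracy, roc_auc = ev$roc_auc,
                 sens_eq_spec = ev$sens_eq_spec)
}))
readr::write_csv(metrics, "results/model_metrics.csv")
cat(sprintf("5-fold CV over %d sampled hospitals: accuracy %.1f%%, ROC AUC %.2f, sens=spec %.2f\n",
            nrow(metrics), 100 * mean(metrics$accuracy),
            mean(metrics$roc_auc), mean(metrics$sens_eq_spec)))

cohort <- build_cohort(patients, 10000, hold, seed = 1001)
bench <- select_benchmark(models, cohort, n_benchmark = 30)
readr::write_csv(bench$cohort_rates, "results/cohort_rates.csv")
writeLines(bench$members, "results/benchmark_members.txt")

agree <- agreement_profile(models, cohort, quorum = 0.8)
cat(sprintf("cohort decisions agreed by 80%% of hospitals: %.0f%% overall (%.0f%% of treated, %.0f%% of untreated)\n",
            100 * agree$overall, 100 * agree$among_treated,
            100 * agree$among_untreated))

bench_rates <- benchmark_rates_all(bench, patients)
readr::write_csv(bench_rates, "results/benchmark_rates.csv")

params <- readr::read_csv("results/pathway_params.csv",
                          show_col_types = FALSE)
common <- intersect(params$hospital_id, bench_rates$hospital_id)
own <- params$p_treat_eligible[match(common, params$hospital_id)]
bmk <- bench_rates$benchmark_rate[match(common, bench_rates$hospital_id)]
cat(sprintf("benchmark vote vs own rate among eligible: %.1f%% vs %.1f%% (weighted by hospital, unweighted mean)\n",
            100 * mean(bmk), 100 * mean(own)))
cat(sprintf("%d of %d benchmark hospitals would treat less under their own benchmark vote\n",
            sum(bmk[match(bench$members, common)] <
                  own[match(bench$members, common)], na.rm = TRUE),
            length(bench$members)))

dir.create("scratch", showWarnings = FALSE)
saveRDS(list(models = models, bench = bench, holdout = hold),
        "scratch/decision_models.rds")
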