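#!/usr/bin/env Rscript
# Step 4: simulate the case-cohort outcome study.
#
# Full cohort under a proportional-hazards truth with clinical covariates
# and six log2-scale biomarkers (three informative, three noise), three
# years of follow-up, all cases kept plus twice as many non-cases with
# Barlow-style weights.
#
# Writes: cohort.csv (sampled case-cohort data) and cohort_truth.csv

library(peaquant)
seed <- 20260904L

log_hr <- c(age = 0.03, smoking = 0.35, diabetes = 0.25,
            bm_cardiac = 0.55, bm_inflam = 0.35, bm_renal = 0.25,
            bm_noise1 = 0, bm_noise2 = 0, bm_noise3 = 0)
truth <- cohort_truth(n_cohort = 5000, baseline_hazard = 0.036,
                      log_hr = log_hr, censor_time = 3,
                      noncase_multiple = 2)
spec <- default_covariate_spec(grep("^bm_", names(log_hr), value = TRUE))
cohort <- simulate_case_cohort(truth, spec, seed = seed)
write_results(cohort, "results/cohort.csv")
write_results(data.frame(covariate = names(log_hr), log_hr = log_hr),
              "results/cohort_truth.csv")

cat(sprintf("cohort: %d subjects sampled from %d (%d cases, %d non-cases, non-case weight %.2f)\n",
            nrow(cohort), truth$n_cohort, sum(cohort$event),
            sum(cohort$event == 0), max(cohort$weight)))
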