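#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Produces, under results/:
#   panel.cfg            - 21-assay panel configuration incl. simulation truth
#   plates_standards.csv - two calibration runs carrying a 30-point two-fold
#                          dilution series per assay (2 replicates total)
#   plates_samples.csv   - four validation plates with patient-like samples,
#                          triplicate calibrators, QC pools, negative controls
#   truth_samples.csv    - hidden true concentrations for later comparison

library(peaquant)
dir.create("results", showWarnings = FALSE)
seed <- 20260901L

truth <- default_assay_truth(ct_noise_sd = 0.1)
panel <- panel_from_truth(truth)
write_panel_config(panel, "results/panel.cfg")

std <- standard_series(truth, n_conc = 30)
plates_std <- simulate_plates(truth, n_plates = 2, n_samples = 30,
                              run_offsets = "random", seed = seed,
                              sample_conc = rbind(std, std))
write_plate_table(plates_std, "results/plates_standards.csv")
write_results(as.data.frame(std), "results/standard_series.csv")

plates <- simulate_plates(truth, n_plates = 4, n_samples = 40,
                          run_offsets = "random", seed = seed + 1L)
write_plate_table(plates, "results/plates_samples.csv")
write_results(attr(plates, "true_conc"), "results/truth_samples.csv")

f <- validate_layout(plates, strict = TRUE)
cat(sprintf("simulated 2 calibration + 4 validation plates (%d assays); strict layout findings: %d\n",
            nrow(truth), nrow(f)))
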