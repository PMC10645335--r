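#!/usr/bin/env Rscript
# Step 2: raw Ct -> NPX -> pg/mL.
#
# Reads the plate tables written by step 1, normalizes them (extension
# control, calibrator ddCt, correction factor), fits the 4PL standard
# curves with LOD/LLOQ/ULOQ, and quantifies the validation samples.
#
# Writes: npx_samples.csv, standard_curves.csv, concentrations.csv

library(peaquant)

panel <- read_panel_config("results/panel.cfg")
truth <- attr(panel, "assay_truth")
std <- as.matrix(read.csv("results/standard_series.csv"))
colnames(std) <- sub("^X", "", colnames(std))  # numeric-safe round trip

plates_std <- read_plate_table("results/plates_standards.csv", panel)
plates <- read_plate_table("results/plates_samples.csv", panel)

npx_std <- npx_from_plate(plates_std)
curves <- fit_standard_curves(npx_std, std, panel)
write_results(curves, "results/standard_curves.csv")

npx <- npx_from_plate(plates)
write_results(npx, "results/npx_samples.csv")

conc <- quantify_samples(npx, curves, panel,
                         roles = c("sample", "qc1", "qc2"))
write_results(conc, "results/concentrations.csv")

ctab <- as.data.frame(curves)
cat(sprintf("fitted %d standard curves; LOD range %.3g-%.3g pg/mL; %d/%d quantitative\n",
            nrow(ctab), min(ctab$lod_conc, na.rm = TRUE),
            max(ctab$lod_conc, na.rm = TRUE),
            sum(ctab$quantitative), nrow(ctab)))
cat(sprintf("quantified %d sample measurements (%.1f%% in range)\n",
            sum(conc$role == "sample"),
            100 * mean(conc$flag[conc$role == "sample"] == "in_range")))
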