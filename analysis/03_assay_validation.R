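#!/usr/bin/env Rscript
# Step 3: analytical validation of the quantified panel.
#
# QC accuracy and intra-assay CV (75-125% acceptance), dynamic-range
# coverage against LLOQ/ULOQ, linearity of dilution on freshly simulated
# mixture plates, method comparison and value reassignment against a
# simulated clinical reference assay.
#
# Writes: qc_report.csv, dynamic_range.csv, linearity.csv,
#         method_comparison.csv, reassignment.csv

library(peaquant)
seed <- 20260903L

panel <- read_panel_config("results/panel.cfg")
truth <- attr(panel, "assay_truth")
conc <- read.csv("results/concentrations.csv")
curves_tab <- read.csv("results/standard_curves.csv")

## QC pools, pooled per chip of two plates -------------------------------
refs <- list(qc1 = setNames(truth$qc1_conc, truth$assay_id),
             qc2 = setNames(truth$qc2_conc, truth$assay_id))
chips <- c(P01 = "chip1", P02 = "chip1", P03 = "chip2", P04 = "chip2")
qc <- qc_report(conc, refs, plate_pairs = chips)
write_results(qc, "results/qc_report.csv")
cat(sprintf("QC: %d pool x chip x assay rows, %.1f%% within 75-125%% acceptance; median CV %.1f%%\n",
            nrow(qc), 100 * mean(qc$pass), median(qc$cv_pct)))

## dynamic range ----------------------------------------------------------
rng <- dynamic_range_report(conc[conc$role == "sample", ])
write_results(rng, "results/dynamic_range.csv")
worst <- rng[which.max(rng$frac_below_lloq), ]
cat(sprintf("dynamic range: median %.1f%% of samples in range; worst assay %s with %.0f%% below LLOQ\n",
            100 * median(rng$frac_in_range), worst$assay_id,
            100 * worst$frac_below_lloq))

## linearity of dilution --------------------------------------------------
std <- as.matrix(read.csv("results/standard_series.csv"))
plates_std <- read_plate_table("results/plates_standards.csv", panel)
curves <- fit_standard_curves(npx_from_plate(plates_std), std, panel)
r <- seq(0, 1, by = 0.25)
high <- exp(truth$sample_logmean + 1.2)   # high endogenous sample
low <- high / 15
mix <- outer(r, high) + outer(1 - r, low)
colnames(mix) <- truth$assay_id
pt_mix <- simulate_plates(truth, n_plates = 1, n_samples = length(r),
                          seed = seed, sample_conc = mix)
q_mix <- quantify_samples(npx_from_plate(pt_mix), curves, panel)
lin <- do.call(rbind, lapply(truth$assay_id, function(aid) {
  qa <- q_mix[q_mix$assay_id == aid, ]
  qa <- qa[order(qa$well_id), ]
  if (anyNA(qa$conc)) return(NULL)
  linearity_analysis(qa$conc[5], qa$conc[1], qa$conc, r, assay_id = aid)
}))
write_results(lin, "results/linearity.csv")
cat(sprintf("linearity: %d assays evaluable, max |relative error| %.1f%%\n",
            length(unique(lin$assay_id)),
            100 * max(abs(lin$relative_error))))

## method comparison + value reassignment for the calibrated assays ------
truth_conc <- read.csv("results/truth_samples.csv")
reassigned <- panel$assays$assay_id[panel$assays$reassigned]
mc_rows <- list(); rs_rows <- list()
for (aid in reassigned) {
  qa <- conc[conc$assay_id == aid & conc$role == "sample" &
               conc$flag == "in_range", ]
  if (nrow(qa) < 10) next
  qa <- merge(qa, truth_conc,
              by = c("plate_id", "well_id", "assay_id", "sample_id"))
  qa <- qa[seq_len(min(40, nrow(qa))), ]   # the 40 bridging samples
  ref <- simulate_reference_assay(qa$true_conc, bias_log2 = 0.35,
                                  noise_log2_sd = 0.25,
                                  seed = seed + match(aid, reassigned))
  mc_rows[[aid]] <- method_comparison(qa$conc, ref, assay_id = aid)
  cv_new <- reassign_values(curves[[aid]], qa$conc, ref)
  rs_rows[[aid]] <- data.frame(assay_id = aid,
                               scale = attr(cv_new, "last_scale"),
                               c_before = curves[[aid]]$c,
                               c_after = cv_new$c)
}
mc <- do.call(rbind, mc_rows)
write_results(mc, "results/method_comparison.csv")
write_results(do.call(rbind, rs_rows), "results/reassignment.csv")
cat(sprintf("method comparison on %d calibrated assays: Spearman rho %.2f-%.2f, r2 %.2f-%.2f\n",
            nrow(mc), min(mc$spearman_rho), max(mc$spearman_rho),
            min(mc$r2), max(mc$r2)))
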