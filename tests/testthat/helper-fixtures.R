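# small fixtures shared across test files; everything is generated in code

small_truth <- function(ct_noise_sd = 0) {
  assay_truth(data.frame(
    assay_id = c("A1", "A2", "A3"),
    a = c(10, 12, 11), d = 0,
    c = c(50, 5, 500), b = c(-1, -1.2, -0.9),
    ct_noise_sd = ct_noise_sd,
    sample_logmean = log(c(400, 40, 4000)),
    sample_logsd = c(0.5, 0.7, 0.4),
    qc1_conc = c(400, 40, 4000), qc2_conc = c(150, 15, 1500)))
}

# tiny single-plate table built by hand (one assay), for I/O and
# normalization arithmetic
tiny_panel <- function(cf = 0) {
  pea_panel("tiny", data.frame(assay_id = "A1", correction_factor = cf))
}

tiny_wells <- function() {
  data.frame(
    plate_id = "P1",
    well_id = sprintf("W%02d", 1:13),
    role = c(rep("calibrator_high", 3), rep("calibrator_middle", 3),
             rep("calibrator_low", 3), rep("calibrator_blank", 3),
             "sample"),
    sample_id = c(rep("", 12), "S1"),
    ext_ctrl_ct = 17,
    ct_A1 = c(19, 19, 19, 21, 21, 21, 23, 23, 23, 25, 25, 25, 20))
}

# brute-force concordance oracle: double loop over ordered pairs
brute_force_c <- function(time, event, score, weights = NULL) {
  n <- length(time)
  if (is.null(weights)) weights <- rep(1, n)
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (event[i] == 1 && time[i] < time[j]) {
      w <- weights[i] * weights[j]
      den <- den + w
      if (score[i] > score[j]) num <- num + w
      else if (score[i] == score[j]) num <- num + 0.5 * w
    }
  }
  num / den
}

# brute-force weighted Breslow partial log-likelihood for a single
# covariate (grid-search oracle)
brute_force_cox_loglik <- function(beta, time, event, x, w) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + w[i] * (beta * x[i] - log(sum(w[risk] * exp(beta * x[risk]))))
  }
  ll
}
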