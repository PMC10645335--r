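#' Per-assay simulation truth
#'
#' Generative counterpart of a fitted standard curve plus the population
#' model for patient samples.  The concentration–response is the
#' four-parameter logistic NPX(x) = d + (a-d)/(1 + (x/c)^b) on the in-well
#' (prediluted) concentration scale; b < 0 gives the physically increasing
#' orientation (more protein, higher NPX).  Patient concentrations (neat
#' scale, pg/mL) are lognormal with log-scale mean `sample_logmean` and SD
#' `sample_logsd`; `qc1_conc`/`qc2_conc` are the true concentrations of the
#' two QC pools; `ct_noise_sd` is the Gaussian measurement noise injected
#' at the Ct level.
#'
#' @param x `data.frame` with columns `assay_id`, `a`, `d`, `c`, `b`,
#'   `ct_noise_sd`, `sample_logmean`, `sample_logsd`, `qc1_conc`, `qc2_conc`.
#' @return The validated data.frame with class `assay_truth`.
#' @export
assay_truth <- function(x) {
  req <- c("assay_id", "a", "d", "c", "b", "ct_noise_sd",
           "sample_logmean", "sample_logsd", "qc1_conc", "qc2_conc")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("assay truth lacks columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[, req]
  x$assay_id <- as.character(x$assay_id)
  if (any(x$a <= x$d)) stop("non-physical truth: upper plateau a must exceed d")
  if (any(x$c <= 0)) stop("inflection concentration c must be positive")
  if (any(x$ct_noise_sd < 0) || any(x$sample_logsd < 0))
    stop("noise standard deviations must be non-negative")
  rownames(x) <- NULL
  class(x) <- c("assay_truth", "data.frame")
  x
}

#' Default 21-assay simulation truth
#'
#' A cardiovascular-marker panel spanning the abundance range seen in
#' plasma: a sub-pg/mL inflammatory cytokine (IL6), mid-range growth
#' factors, high-abundance markers (CST3, TFF3), and one deliberately
#' desensitized assay (TNNI3, inflection far above circulating levels) that
#' reproduces the below-LLOQ failure mode of a cardiac troponin assay under
#' ten-fold predilution.  Five assays are flagged for value reassignment to
#' clinical reference methods.
#'
#' @param ct_noise_sd Ct-level noise SD (cycles) applied to every assay.
#' @return An [assay_truth()] table with 21 rows.
#' @export
default_assay_truth <- function(ct_noise_sd = 0.1) {
  ids <- c("ADM", "CHI3L1", "CST3", "FGF23", "GDF15", "HGF", "IL6", "KIM1",
           "MMP12", "NTproBNP", "OPG", "OPN", "REN", "SCF", "SPON1", "ST2",
           "TFF3", "TNNI3", "TRAILR2", "UPAR", "VEGFD")
  # inflection c on the in-well scale; sample_logmean on the neat scale
  c_infl <- c(20, 400, 8000, 15, 120, 60, 0.15, 25,
              800, 4, 300, 3000, 40, 90, 1500, 900,
              6000, 500, 1.5, 8, 30)
  meanlog <- log(c(180, 4000, 9e4, 120, 1300, 600, 2.5, 180,
                   9000, 60, 3200, 3e4, 420, 900, 1.6e4, 9000,
                   6e4, 8, 18, 90, 320))
  sdlog <- c(0.5, 0.6, 0.35, 0.7, 0.6, 0.5, 0.9, 0.8,
             0.5, 1.1, 0.4, 0.5, 0.9, 0.4, 0.4, 0.5,
             0.45, 1.0, 0.5, 0.5, 0.7)
  assay_truth(data.frame(
    assay_id = ids,
    a = 10 + (seq_along(ids) %% 5),
    d = 0,
    c = c_infl,
    b = -1 - 0.1 * (seq_along(ids) %% 4),
    ct_noise_sd = ct_noise_sd,
    sample_logmean = meanlog,
    sample_logsd = sdlog,
    qc1_conc = exp(meanlog),
    qc2_conc = exp(meanlog - 1)))
}

#' Evaluate the four-parameter logistic response
#'
#' @param x Concentration(s), same scale as `c`.
#' @param a,d Upper and lower NPX plateaus (a > d).
#' @param c Inflection concentration.
#' @param b Slope; negative for an increasing concentration-response.
#' @return NPX value(s); `x = 0` returns the zero-concentration asymptote.
#' @export
fourpl <- function(x, a, d, c, b) {
  r <- (x / c)^b               # 0^b = Inf for b < 0, giving NPX(0) = d
  d + (a - d) / (1 + r)
}

#' Build a panel configuration from simulation truth
#'
#' The per-assay correction factor is set to the mean calibrator NPX under
#' the truth (mean of the responses at the High/Middle/Low calibrator
#' concentrations), which makes the normalized NPX of a noiseless simulated
#' well equal the true concentration-response exactly.
#'
#' @param truth An [assay_truth()] table.
#' @param panel_name Panel label.
#' @param predilution_factor Sample predilution (default 10).
#' @param reassigned Character vector of assay ids calibrated against
#'   clinical reference methods.
#' @return A [pea_panel()] carrying `truth` as the `assay_truth` attribute.
#' @export
panel_from_truth <- function(truth, panel_name = "cardio21-sim",
                             predilution_factor = 10,
                             reassigned = c("IL6", "GDF15", "CST3",
                                            "NTproBNP", "TNNI3")) {
  stopifnot(inherits(truth, "assay_truth"))
  cf <- vapply(seq_len(nrow(truth)), function(i) {
    with(truth[i, ], mean(fourpl(c(16 * c, c, c / 16), a, d, c, b)))
  }, numeric(1L))
  panel <- pea_panel(panel_name, data.frame(
    assay_id = truth$assay_id,
    unit = "pg/mL",
    predilution_factor = predilution_factor,
    correction_factor = cf,
    reassigned = truth$assay_id %in% reassigned))
  attr(panel, "assay_truth") <- truth
  panel
}

#' Simulate multiplex PEA plates
#'
#' Each plate carries triplicate High/Middle/Low/Blank calibrators
#' (true in-well concentrations 16c, c, c/16 and 0 per assay), triplicate
#' QC1/QC2 pools, triplicate negative controls, and `n_samples` patient
#' wells.  The observed Ct of a well is
#' `ext_ctrl_ct + base_dct - NPX_true(conc) + noise` where the extension
#' control carries the per-plate run offset and per-well technical shift,
#' so normalization has real cancellation work to do.  Noise is Gaussian at
#' the Ct level with per-assay SD.
#'
#' @param truth An [assay_truth()] table.
#' @param n_plates Number of plates (runs).
#' @param n_samples Patient sample wells per plate.
#' @param run_offsets Per-plate additive Ct offset; a numeric vector
#'   recycled over plates, or `"random"` for N(0, 0.5) offsets.
#' @param seed Integer seed; all randomness derives from it.
#' @param sample_conc Optional true neat-scale concentrations for the
#'   sample wells: a matrix/data.frame of `n_plates * n_samples` rows (one
#'   per sample well, plates stacked) with one column per assay.  Used to
#'   lay standard dilution series onto plates; default draws lognormal
#'   patient concentrations from the truth.
#' @param panel Panel configuration; default [panel_from_truth()].
#' @param base_dct Anchor dCt for the coding of NPX into Ct (cancels in
#'   normalization).  The default places every Ct in the 16-31 cycle range
#'   typical of microfluidic qPCR.
#' @return The [plate_table()], with attributes `true_conc` (data.frame of
#'   hidden neat-scale truths per plate/well/assay for recovery tests),
#'   `run_offsets`, and `seed`.
#' @export
simulate_plates <- function(truth, n_plates = 1L, n_samples = 8L,
                            run_offsets = 0, seed = 1L,
                            sample_conc = NULL,
                            panel = panel_from_truth(truth),
                            base_dct = 13) {
  stopifnot(inherits(truth, "assay_truth"), n_plates >= 1L)
  set.seed(seed)
  n_assays <- nrow(truth)
  if (identical(run_offsets, "random")) {
    offsets <- stats::rnorm(n_plates, 0, 0.5)
  } else {
    offsets <- rep_len(as.numeric(run_offsets), n_plates)
  }
  roles <- c(rep(c("calibrator_high", "calibrator_middle", "calibrator_low",
                   "calibrator_blank", "qc1", "qc2", "negative_control"),
                 each = 3L),
             rep("sample", n_samples))
  n_wells <- length(roles)
  well_sd <- mean(truth$ct_noise_sd)
  predil <- panel$assays$predilution_factor[
    match(truth$assay_id, panel$assays$assay_id)]

  plates <- vector("list", n_plates)
  truths <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    pid <- sprintf("P%02d", p)
    well_id <- sprintf("W%02d", seq_len(n_wells))
    sample_id <- ifelse(roles == "sample",
                        sprintf("%s_S%02d", pid, cumsum(roles == "sample")),
                        "")
    well_base <- 17 + offsets[p] + stats::rnorm(n_wells, 0, well_sd)
    ct <- matrix(NA_real_, n_wells, n_assays,
                 dimnames = list(NULL, paste0("ct_", truth$assay_id)))
    conc_true <- matrix(NA_real_, n_wells, n_assays,
                        dimnames = list(NULL, truth$assay_id))
    samp_rows <- which(roles == "sample")
    for (j in seq_len(n_assays)) {
      tj <- truth[j, ]
      conc_well <- numeric(n_wells)           # in-well scale
      conc_well[roles == "calibrator_high"]   <- 16 * tj$c
      conc_well[roles == "calibrator_middle"] <- tj$c
      conc_well[roles == "calibrator_low"]    <- tj$c / 16
      conc_well[roles %in% c("calibrator_blank", "negative_control")] <- 0
      conc_well[roles == "qc1"] <- tj$qc1_conc / predil[j]
      conc_well[roles == "qc2"] <- tj$qc2_conc / predil[j]
      if (is.null(sample_conc)) {
        neat <- stats::rlnorm(n_samples, tj$sample_logmean, tj$sample_logsd)
      } else {
        idx <- (p - 1L) * n_samples + seq_len(n_samples)
        neat <- as.numeric(as.matrix(sample_conc)[idx, truth$assay_id[j]])
      }
      conc_well[samp_rows] <- neat / predil[j]
      npx_true <- fourpl(conc_well, tj$a, tj$d, tj$c, tj$b)
      ct[, j] <- well_base + base_dct - npx_true +
        stats::rnorm(n_wells, 0, tj$ct_noise_sd)
      conc_true[, j] <- conc_well * predil[j]   # report truth on neat scale
    }
    plates[[p]] <- data.frame(plate_id = pid, well_id = well_id,
                              role = roles, sample_id = sample_id,
                              ext_ctrl_ct = well_base, ct,
                              check.names = FALSE)
    tr <- data.frame(plate_id = pid, well_id = rep(well_id, n_assays),
                     sample_id = rep(sample_id, n_assays),
                     role = rep(roles, n_assays),
                     assay_id = rep(truth$assay_id, each = n_wells),
                     true_conc = as.vector(conc_true))
    truths[[p]] <- tr[tr$role %in% c("sample", "qc1", "qc2"), ]
  }
  out <- plate_table(panel, do.call(rbind, plates))
  tt <- do.call(rbind, truths)
  rownames(tt) <- NULL
  attr(out, "true_conc") <- tt
  attr(out, "run_offsets") <- offsets
  attr(out, "seed") <- seed
  out
}

#' Standard dilution series as sample-well concentrations
#'
#' Builds the neat-scale concentration matrix for [simulate_plates()]'s
#' `sample_conc` argument: per assay a two-fold dilution series of
#' `n_conc` points starting `top_multiple` above the inflection (in-well
#' scale), repeated for every replicate well on the plate.
#'
#' @param truth An [assay_truth()] table.
#' @param n_conc Number of dilution points (wells per plate).
#' @param top_multiple Top standard as a multiple of the inflection c.
#' @param predilution Predilution factor used to express the neat scale.
#' @return Matrix `n_conc x n_assays` of neat-scale concentrations, with
#'   assay ids as column names.
#' @export
standard_series <- function(truth, n_conc = 30L, top_multiple = 64,
                            predilution = 10) {
  stopifnot(inherits(truth, "assay_truth"))
  m <- sapply(seq_len(nrow(truth)), function(j)
    truth$c[j] * top_multiple * 2^(-(seq_len(n_conc) - 1L)) * predilution)
  colnames(m) <- truth$assay_id
  m
}

#' Simulate a standard-curve experiment at the NPX level
#'
#' Generates the calibration design of `n_runs` runs x `n_replicates`
#' replicates x `n_conc` two-fold dilutions plus blanks, with Gaussian
#' noise on NPX.  Concentrations are on the in-well scale.
#'
#' @param tj One row of an [assay_truth()] table.
#' @param n_conc,n_replicates,n_runs Design size (defaults 30 x 2 x 2).
#' @param top_multiple Top standard as a multiple of the inflection.
#' @param npx_noise_sd NPX-level noise SD.
#' @param n_blanks Blank wells per run.
#' @param seed Integer seed.
#' @return data.frame with columns `run`, `conc` (in-well scale), `npx`.
#' @export
simulate_standard_curve <- function(tj, n_conc = 30L, n_replicates = 2L,
                                    n_runs = 2L, top_multiple = 64,
                                    npx_noise_sd = 0.1, n_blanks = 3L,
                                    seed = 1L) {
  set.seed(seed)
  conc1 <- tj$c * top_multiple * 2^(-(seq_len(n_conc) - 1L))
  conc <- rep(c(rep(conc1, n_replicates), rep(0, n_blanks)), n_runs)
  run <- rep(seq_len(n_runs), each = n_conc * n_replicates + n_blanks)
  npx <- fourpl(conc, tj$a, tj$d, tj$c, tj$b) +
    stats::rnorm(length(conc), 0, npx_noise_sd)
  data.frame(run = run, conc = conc, npx = npx)
}

#' Simulate a reference-assay measurement of known concentrations
#'
#' Reference value = truth x 2^(bias_log2 + e), e ~ N(0, noise_log2_sd):
#' a multiplicative method bias plus lognormal measurement error, the
#' structure assumed by the method-comparison statistics.
#'
#' @param truth_conc Positive true concentrations.
#' @param bias_log2 Systematic log2 bias of the reference method.
#' @param noise_log2_sd Log2-scale measurement noise SD.
#' @param seed Integer seed.
#' @return Numeric vector of reference concentrations.
#' @export
simulate_reference_assay <- function(truth_conc, bias_log2 = 0,
                                     noise_log2_sd = 0.1, seed = 1L) {
  if (any(truth_conc <= 0)) stop("true concentrations must be positive")
  if (noise_log2_sd < 0) stop("noise SD must be non-negative")
  set.seed(seed)
  truth_conc * 2^(bias_log2 + stats::rnorm(length(truth_conc), 0, noise_log2_sd))
}
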