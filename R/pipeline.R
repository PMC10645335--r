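#' Fit standard curves for every assay from a calibration run
#'
#' Takes the normalized NPX of plates whose sample wells carry a known
#' standard dilution series (see [standard_series()]), fits the 4PL per
#' assay with negative-control wells as blanks, and determines LOD (blank
#' mean + 3 SD) and LLOQ/ULOQ (30% accuracy/precision rule) on the
#' neat-sample scale.
#'
#' @param npx_std Long NPX table of the calibration plates (from
#'   [npx_from_plate()]); sample wells are the standards, negative-control
#'   wells the blanks.
#' @param nominal Matrix of neat-scale nominal concentrations, one row per
#'   standard well (plates stacked in plate/well order), one named column
#'   per assay — the `sample_conc` argument given to [simulate_plates()].
#' @param panel The [pea_panel()] (predilution factors).
#' @return A [standard_curve_set()].
#' @export
fit_standard_curves <- function(npx_std, nominal, panel) {
  nominal <- as.matrix(nominal)
  curves <- lapply(colnames(nominal), function(aid) {
    s <- npx_std[npx_std$role == "sample" & npx_std$assay_id == aid, ]
    s <- s[order(s$plate_id, s$well_id), ]
    blanks <- npx_std$npx[npx_std$role == "negative_control" &
                            npx_std$assay_id == aid]
    predil <- panel$assays$predilution_factor[
      panel$assays$assay_id == aid]
    n_rep <- nrow(s) / nrow(nominal)
    if (n_rep != round(n_rep))
      stop("standard wells of ", aid,
           " are not a whole number of series replicates")
    conc_well <- rep(nominal[, aid], n_rep) / predil
    cv <- fit_4pl(c(conc_well, rep(0, length(blanks))),
                  c(s$npx, blanks), assay_id = aid)
    cv <- determine_lod(cv, blanks, predilution = predil)
    determine_loq(cv, conc_well, s$npx, predilution = predil)
  })
  standard_curve_set(curves)
}
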