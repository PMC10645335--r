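#' Linearity-of-dilution analysis
#'
#' A high- and a low-concentration native sample are mixed at fractions r
#' to give equally spaced intermediate concentrations.  The theoretical
#' concentration of each mixture is r * high + (1 - r) * low from the
#' *measured* endpoint concentrations; the relative error of a mixture is
#' (measured - theoretical) / theoretical.
#'
#' @param high_conc,low_conc Measured concentrations of the endpoint
#'   samples (`high_conc > low_conc > 0`).
#' @param measured Measured concentrations of the mixtures.
#' @param ratios Mixing fractions of the high sample, in `[0, 1]`, same
#'   length as `measured`.
#' @param assay_id Optional assay label.
#' @return data.frame with `assay_id`, `ratio`, `measured`, `theoretical`,
#'   `relative_error`, plus attributes `max_abs_relative_error` and
#'   `mean_relative_error` (signed).
#' @export
linearity_analysis <- function(high_conc, low_conc, measured, ratios,
                               assay_id = NA_character_) {
  if (!(high_conc > low_conc && low_conc > 0))
    stop("need high_conc > low_conc > 0")
  if (any(ratios < 0 | ratios > 1)) stop("mixing ratios must lie in [0, 1]")
  stopifnot(length(measured) == length(ratios))
  theoretical <- ratios * high_conc + (1 - ratios) * low_conc
  if (any(theoretical <= 0)) stop("non-positive theoretical concentration")
  rel <- (measured - theoretical) / theoretical
  out <- data.frame(assay_id = assay_id, ratio = ratios,
                    measured = measured, theoretical = theoretical,
                    relative_error = rel)
  attr(out, "max_abs_relative_error") <- max(abs(rel))
  attr(out, "mean_relative_error") <- mean(rel)
  out
}

#' QC accuracy and intra-assay precision
#'
#' accuracy = mean(replicates) / reference * 100; CV = sample SD /
#' mean * 100.  The acceptance flag is true exactly when accuracy lies in
#' \[75, 125\]%.  Replicates are typically pooled per chip (6 = 2 plates x
#' 3) or per plate (3).
#'
#' @param replicates At least 2 positive QC concentration values.
#' @param reference Reference concentration of the QC pool (> 0).
#' @return One-row data.frame: `accuracy_pct`, `cv_pct`, `pass`.
#' @export
qc_metrics <- function(replicates, reference) {
  replicates <- replicates[is.finite(replicates)]
  if (length(replicates) < 2L) stop("need at least 2 QC replicates")
  if (!(reference > 0)) stop("QC reference value must be positive")
  if (any(replicates <= 0)) stop("QC replicates must be positive")
  m <- mean(replicates)
  acc <- m / reference * 100
  cv <- stats::sd(replicates) / m * 100
  data.frame(accuracy_pct = acc, cv_pct = cv,
             pass = acc >= 75 & acc <= 125)
}

#' Per-plate (or per-chip) QC report across a quantification table
#'
#' @param quant Quantification table from [quantify_samples()] run with
#'   `roles = c("qc1", "qc2")`.
#' @param references Named list/vector per pool (`qc1`, `qc2`) of per-assay
#'   named reference concentrations.
#' @param plate_pairs Optional named vector mapping `plate_id` to a chip
#'   label; when given, replicates are pooled per chip (6 per pool),
#'   otherwise per plate (3).
#' @return data.frame: `group`, `assay_id`, `pool`, `n`, `accuracy_pct`,
#'   `cv_pct`, `pass`.
#' @export
qc_report <- function(quant, references, plate_pairs = NULL) {
  grp <- if (is.null(plate_pairs)) quant$plate_id
         else unname(plate_pairs[quant$plate_id])
  out <- list()
  for (g in unique(grp)) {
    qg <- quant[grp == g, ]
    for (aid in unique(qg$assay_id)) {
      for (p in intersect(c("qc1", "qc2"), unique(qg$role))) {
        reps <- qg$conc[qg$assay_id == aid & qg$role == p]
        reps <- reps[is.finite(reps)]
        if (length(reps) < 2L) next
        ref <- references[[p]][[aid]]
        if (is.null(ref) || !is.finite(ref)) next
        row <- qc_metrics(reps, ref)
        out[[length(out) + 1L]] <- data.frame(
          group = g, assay_id = aid, pool = p, n = length(reps), row)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dynamic-range coverage report
#'
#' Per assay, the fractions of quantified samples below LLOQ (including
#' below LOD), above ULOQ, and within range; the three fractions sum to 1.
#'
#' @param quant Quantification table from [quantify_samples()].
#' @return data.frame: `assay_id`, `n`, `n_below`, `n_above`, `n_in_range`,
#'   `frac_below_lloq`, `frac_above_uloq`, `frac_in_range`.
#' @export
dynamic_range_report <- function(quant) {
  out <- lapply(split(quant, quant$assay_id), function(qa) {
    n <- nrow(qa)
    nb <- sum(qa$flag %in% c("below_lloq", "below_lod"))
    na_ <- sum(qa$flag == "above_uloq")
    ni <- sum(qa$flag == "in_range")
    data.frame(assay_id = qa$assay_id[1L], n = n, n_below = nb,
               n_above = na_, n_in_range = ni,
               frac_below_lloq = nb / n, frac_above_uloq = na_ / n,
               frac_in_range = ni / n)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Method comparison against a reference assay
#'
#' Spearman rank correlation (average ranks on ties), squared Pearson
#' correlation of the log2 values, and Bland-Altman agreement statistics of
#' the paired log2 differences (pea - reference) with 1.96 SD limits.
#'
#' @param pea Concentrations from the PEA quantification (> 0).
#' @param reference Paired reference-assay concentrations (> 0).
#' @param assay_id Optional assay label.
#' @return One-row data.frame: `assay_id`, `n`, `spearman_rho`, `r2`,
#'   `ba_mean`, `ba_sd`, `ba_lower`, `ba_upper`.
#' @export
method_comparison <- function(pea, reference, assay_id = NA_character_) {
  stopifnot(length(pea) == length(reference))
  ok <- is.finite(pea) & is.finite(reference)
  pea <- pea[ok]; reference <- reference[ok]
  if (length(pea) < 3L) stop("need at least 3 paired samples")
  if (any(pea <= 0) || any(reference <= 0))
    stop("method comparison requires positive concentrations (log2 scale)")
  lp <- log2(pea); lr <- log2(reference)
  rho <- stats::cor(pea, reference, method = "spearman")
  r2 <- stats::cor(lp, lr, method = "pearson")^2
  dif <- lp - lr
  ba_mean <- mean(dif)
  ba_sd <- stats::sd(dif)
  data.frame(assay_id = assay_id, n = length(pea), spearman_rho = rho,
             r2 = r2, ba_mean = ba_mean, ba_sd = ba_sd,
             ba_lower = ba_mean - 1.96 * ba_sd,
             ba_upper = ba_mean + 1.96 * ba_sd)
}
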