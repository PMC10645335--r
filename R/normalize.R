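#' Within-run normalization: extension-control subtraction
#'
#' dCt = Ct - Ct(extension control), per well and assay.  The extension
#' control is an internal per-well assay, so any additive technical shift
#' affecting all assays of a well cancels exactly.
#'
#' @param t A [plate_table()].
#' @return Long data.frame: `plate_id`, `well_id`, `sample_id`, `role`,
#'   `assay_id`, `ct`, `dct`.  Missing Ct propagates to missing dCt.
#' @export
compute_dct <- function(t) {
  stopifnot(inherits(t, "plate_table"))
  w <- t$wells
  assays <- t$panel$assays$assay_id
  ct_cols <- paste0("ct_", assays)
  any_ct <- rowSums(!is.na(as.matrix(w[, ct_cols, drop = FALSE]))) > 0L
  bad <- which(!is.finite(w$ext_ctrl_ct) & any_ct)
  if (length(bad))
    stop("well ", w$well_id[bad[1L]], " on plate ", w$plate_id[bad[1L]],
         " has finite Ct but no extension-control Ct")
  out <- do.call(rbind, lapply(seq_along(assays), function(j) {
    data.frame(plate_id = w$plate_id, well_id = w$well_id,
               sample_id = w$sample_id, role = w$role,
               assay_id = assays[j], ct = w[[ct_cols[j]]],
               dct = w[[ct_cols[j]]] - w$ext_ctrl_ct)
  }))
  rownames(out) <- NULL
  out
}

#' Between-run calibrator summary
#'
#' Per plate and assay: the median of each non-blank calibrator triplicate
#' (High, Middle, Low) and their mean, the quantity subtracted in the
#' between-run normalization step.  The median of an even replicate count
#' is the midpoint of the two central values.
#'
#' @param dct Long dCt table from [compute_dct()].
#' @param plate_id Plate to summarize; default all plates.
#' @return data.frame with `plate_id`, `assay_id`, `dct_high`, `dct_middle`,
#'   `dct_low`, `dct_cal` (= mean of the three medians).
#' @export
summarize_calibrators <- function(dct, plate_id = NULL) {
  if (!is.null(plate_id)) dct <- dct[dct$plate_id %in% plate_id, ]
  lev <- c(high = "calibrator_high", middle = "calibrator_middle",
           low = "calibrator_low")
  out <- list()
  for (pid in sort(unique(dct$plate_id))) {
    dp <- dct[dct$plate_id == pid, ]
    for (aid in unique(dp$assay_id)) {
      da <- dp[dp$assay_id == aid, ]
      med <- vapply(lev, function(r) {
        v <- da$dct[da$role == r]
        v <- v[!is.na(v)]
        if (!length(v))
          stop("plate ", pid, " assay ", aid, " lacks ", r,
               " wells; run validate_layout()")
        stats::median(v)
      }, numeric(1L))
      out[[length(out) + 1L]] <- data.frame(
        plate_id = pid, assay_id = aid,
        dct_high = med[["high"]], dct_middle = med[["middle"]],
        dct_low = med[["low"]], dct_cal = mean(med))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Convert dCt to NPX
#'
#' ddCt = dCt - dct_cal (between-run normalization against the plate's
#' calibrator summary); NPX = correction_factor - ddCt.  The sign makes NPX
#' increase with protein level (more template, lower Ct), on a log2 scale
#' with background near zero when the correction factor is blank-anchored.
#'
#' ddCt is evaluated as the mean of the three per-level differences
#' `dct - median(level)` rather than `dct - mean(medians)`: the two forms
#' are algebraically identical, but the difference-first form makes a
#' plate-wide additive Ct shift cancel *bit-exactly* (the shift leaves each
#' subtraction unchanged before any aggregation rounds).
#'
#' @param dct Long dCt table from [compute_dct()].
#' @param cal Calibrator summary from [summarize_calibrators()].
#' @param panel The [pea_panel()] supplying per-assay correction factors;
#'   alternatively a named numeric vector of correction factors.
#' @return Long NPX table: `plate_id`, `well_id`, `sample_id`, `role`,
#'   `assay_id`, `dct`, `ddct`, `npx`.
#' @export
to_npx <- function(dct, cal, panel) {
  if (inherits(panel, "pea_panel")) {
    cf <- stats::setNames(panel$assays$correction_factor,
                          panel$assays$assay_id)
  } else {
    cf <- panel
  }
  miss <- setdiff(unique(dct$assay_id), names(cf))
  if (length(miss))
    stop("no correction factor configured for assay(s): ",
         paste(miss, collapse = ", "))
  key <- paste(dct$plate_id, dct$assay_id, sep = "\r")
  cal_key <- paste(cal$plate_id, cal$assay_id, sep = "\r")
  idx <- match(key, cal_key)
  if (anyNA(idx))
    stop("no calibrator summary for plate/assay: ",
         key[which(is.na(idx))[1L]])
  out <- dct
  out$ddct <- ((dct$dct - cal$dct_high[idx]) +
               (dct$dct - cal$dct_middle[idx]) +
               (dct$dct - cal$dct_low[idx])) / 3
  out$npx <- cf[dct$assay_id] - out$ddct
  rownames(out) <- NULL
  out
}

#' Full plate-to-NPX normalization
#'
#' Convenience wrapper running [compute_dct()], [summarize_calibrators()]
#' and [to_npx()] on a plate table.
#'
#' @param t A [plate_table()].
#' @return Long NPX table (see [to_npx()]).
#' @export
npx_from_plate <- function(t) {
  d <- compute_dct(t)
  to_npx(d, summarize_calibrators(d), t$panel)
}

#' Pivot a long NPX table to a sample-by-assay matrix
#'
#' @param npx Long NPX table from [to_npx()].
#' @param roles Well roles to include (default samples only).
#' @return Numeric matrix, rows named `plate|well|sample`, one column per
#'   assay.
#' @export
npx_matrix <- function(npx, roles = "sample") {
  npx <- npx[npx$role %in% roles, ]
  rid <- paste(npx$plate_id, npx$well_id, npx$sample_id, sep = "|")
  rows <- unique(rid)
  cols <- unique(npx$assay_id)
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  m[cbind(match(rid, rows), match(npx$assay_id, cols))] <- npx$npx
  m
}
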