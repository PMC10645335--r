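ROLE_LEVELS <- c("sample", "calibrator_high", "calibrator_middle",
                 "calibrator_low", "calibrator_blank", "qc1", "qc2",
                 "negative_control")

CAL_ROLES <- c("calibrator_high", "calibrator_middle", "calibrator_low",
               "calibrator_blank")

#' Construct a plate table
#'
#' Wide per-well representation of a multiplex qPCR run: one row per
#' (plate, well) with the per-well extension-control Ct and one `ct_<assay>`
#' column per panel assay.  Missing Ct values are `NA`.
#'
#' @param panel A [pea_panel()].
#' @param wells `data.frame` with columns `plate_id`, `well_id`, `role`,
#'   `sample_id`, `ext_ctrl_ct` and `ct_<assay_id>` for every panel assay.
#' @return Object of class `plate_table` (list with `panel` and `wells`).
#' @export
plate_table <- function(panel, wells) {
  stopifnot(inherits(panel, "pea_panel"), is.data.frame(wells))
  req <- c("plate_id", "well_id", "role", "sample_id", "ext_ctrl_ct")
  miss <- setdiff(req, names(wells))
  if (length(miss))
    stop("plate table is missing required columns: ", paste(miss, collapse = ", "))
  ct_cols <- paste0("ct_", panel$assays$assay_id)
  miss_ct <- setdiff(ct_cols, names(wells))
  if (length(miss_ct))
    stop("plate table is missing assay Ct columns: ",
         paste(miss_ct, collapse = ", "))
  wells$role <- tolower(as.character(wells$role))
  bad <- which(!wells$role %in% ROLE_LEVELS)
  if (length(bad))
    stop("unknown well role '", wells$role[bad[1L]], "' in row ", bad[1L])
  if (any(!is.finite(wells$ext_ctrl_ct)))
    stop("ext_ctrl_ct must be finite for every well")
  wells <- wells[order(wells$plate_id, wells$well_id), , drop = FALSE]
  rownames(wells) <- NULL
  structure(list(panel = panel,
                 wells = wells[, c(req, ct_cols), drop = FALSE]),
            class = "plate_table")
}

#' @export
print.plate_table <- function(x, ...) {
  cat("plate_table:", length(unique(x$wells$plate_id)), "plate(s),",
      nrow(x$wells), "wells,", nrow(x$panel$assays), "assays\n")
  print(table(x$wells$plate_id, x$wells$role))
  invisible(x)
}

#' Read a plate table from CSV
#'
#' The dialect is UTF-8 comma-separated, one row per (plate, well), with
#' columns `plate_id`, `well_id`, `role`, `sample_id`, `ext_ctrl_ct` and
#' one `ct_<assay>` column per assay; missing Ct is the literal `NA`.
#' Role labels are case-insensitive on read.  Unparseable Ct entries are
#' recorded as missing with a warning.
#'
#' @param path CSV file path.
#' @param panel The [pea_panel()] describing the expected assay columns.
#' @return A [plate_table()].
#' @export
read_plate_table <- function(path, panel) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  req <- c("plate_id", "well_id", "role", "sample_id", "ext_ctrl_ct")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("plate file ", path, " lacks required columns: ",
         paste(miss, collapse = ", "))
  num_cols <- c("ext_ctrl_ct", grep("^ct_", names(raw), value = TRUE))
  for (cc in num_cols) {
    parsed <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- !is.na(raw[[cc]]) & raw[[cc]] != "NA" & is.na(parsed)
    if (any(bad))
      warning(sum(bad), " unparseable value(s) in column ", cc,
              " recorded as missing", call. = FALSE)
    raw[[cc]] <- parsed
  }
  raw$sample_id[is.na(raw$sample_id)] <- ""
  plate_table(panel, raw)
}

#' Write a plate table to CSV
#'
#' Numeric values are written with 17 significant digits so a
#' write/read round trip reproduces every double bit-identically.
#'
#' @param t A [plate_table()].
#' @param path Output CSV path.
#' @export
write_plate_table <- function(t, path) {
  stopifnot(inherits(t, "plate_table"))
  out <- t$wells
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.17g", v)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Check plate layout against the calibrator/QC design
#'
#' Every plate must carry all four calibrator levels; under `strict = TRUE`
#' they (and any QC pools present) must appear in triplicate, matching the
#' run design of triplicate High/Middle/Low/Blank calibrators.
#'
#' @param t A [plate_table()].
#' @param strict Require exact triplicates rather than mere presence.
#' @return A data.frame of findings (zero rows when the layout conforms)
#'   with columns `plate_id`, `role`, `n_observed`, `n_expected`, `message`.
#' @export
validate_layout <- function(t, strict = FALSE) {
  stopifnot(inherits(t, "plate_table"))
  findings <- list()
  for (pid in sort(unique(t$wells$plate_id))) {
    roles <- t$wells$role[t$wells$plate_id == pid]
    for (r in CAL_ROLES) {
      n <- sum(roles == r)
      if (n == 0L)
        findings[[length(findings) + 1L]] <- data.frame(
          plate_id = pid, role = r, n_observed = 0L, n_expected = 1L,
          message = sprintf("plate %s lacks %s", pid, r))
      else if (strict && n != 3L)
        findings[[length(findings) + 1L]] <- data.frame(
          plate_id = pid, role = r, n_observed = n, n_expected = 3L,
          message = sprintf("plate %s has %d %s wells, expected triplicate",
                            pid, n, r))
    }
    if (strict) {
      for (r in c("qc1", "qc2")) {
        n <- sum(roles == r)
        if (n > 0L && n != 3L)
          findings[[length(findings) + 1L]] <- data.frame(
            plate_id = pid, role = r, n_observed = n, n_expected = 3L,
            message = sprintf("plate %s has %d %s wells, expected triplicate",
                              pid, n, r))
      }
    }
  }
  if (!length(findings))
    return(data.frame(plate_id = character(), role = character(),
                      n_observed = integer(), n_expected = integer(),
                      message = character()))
  do.call(rbind, findings)
}

#' Write a pipeline result to CSV
#'
#' Deterministic column order and number formatting (17 significant digits,
#' lossless well beyond the documented 12), so results re-read identically.
#' Accepts the documented result data.frames (NPX tables, quantification
#' results, validation reports) and standard-curve collections.
#'
#' @param obj A result `data.frame` or a `standard_curve_set`.
#' @param path Output CSV path.
#' @export
write_results <- function(obj, path) {
  if (inherits(obj, "standard_curve_set")) obj <- as.data.frame(obj)
  if (!is.data.frame(obj))
    stop("write_results handles result data.frames and standard curve sets")
  out <- obj
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.17g", v)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}
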