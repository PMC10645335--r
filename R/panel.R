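#' Assay panel configuration
#'
#' A panel bundles the per-assay definitions shared by every pipeline stage:
#' reporting unit, predilution factor (10 for plasma panels of this design),
#' the log2-scale correction factor entering NPX, and whether the assay is
#' value-reassigned against a clinical reference method.
#'
#' @param panel_name Single string naming the panel.
#' @param assays `data.frame` with columns `assay_id`, `unit`,
#'   `predilution_factor`, `correction_factor`, `reassigned`.  Missing
#'   optional columns are filled with defaults (unit `"pg/mL"`, predilution
#'   10, correction factor 0, reassigned `FALSE`).
#' @return An object of class `pea_panel`: a list with `panel_name`,
#'   `assays` (data.frame) and `calibrator_levels` (the four fixed labels
#'   `high`, `middle`, `low`, `blank`).
#' @examples
#' pea_panel("demo", data.frame(assay_id = c("IL6", "GDF15")))
#' @export
pea_panel <- function(panel_name, assays) {
  stopifnot(is.character(panel_name), length(panel_name) == 1L)
  if (!is.data.frame(assays) || nrow(assays) < 1L)
    stop("a panel needs at least one assay")
  if (!"assay_id" %in% names(assays))
    stop("assay table must have an 'assay_id' column")
  assays$assay_id <- as.character(assays$assay_id)
  if (anyDuplicated(assays$assay_id))
    stop("assay_id must be unique within a panel")
  if (is.null(assays$unit)) assays$unit <- "pg/mL"
  if (is.null(assays$predilution_factor)) assays$predilution_factor <- 10
  if (is.null(assays$correction_factor)) assays$correction_factor <- 0
  if (is.null(assays$reassigned)) assays$reassigned <- FALSE
  if (any(!is.finite(assays$predilution_factor)) ||
      any(assays$predilution_factor <= 0))
    stop("predilution_factor must be positive and finite")
  rownames(assays) <- NULL
  structure(
    list(panel_name = panel_name,
         assays = assays[, c("assay_id", "unit", "predilution_factor",
                             "correction_factor", "reassigned")],
         calibrator_levels = c("high", "middle", "low", "blank")),
    class = "pea_panel")
}

#' @export
print.pea_panel <- function(x, ...) {
  cat("PEA panel '", x$panel_name, "': ", nrow(x$assays), " assays\n", sep = "")
  print(utils::head(x$assays, 10))
  invisible(x)
}

#' Read or write a panel configuration file
#'
#' The panel file is a flat key-value (Debian-control / DCF) file with one
#' block per assay plus a leading header block carrying `panel_name`.
#' Simulation-truth keys (`a`, `d`, `c`, `b`, `ct_noise_sd`,
#' `sample_logmean`, `sample_logsd`, `qc1_conc`, `qc2_conc`), when present,
#' are preserved so the same file can drive [simulate_plates()].
#'
#' @param path File path.
#' @param panel A `pea_panel`, optionally with an `assay_truth` attribute
#'   (see [assay_truth()]) whose columns are written alongside.
#' @return `read_panel_config` returns a `pea_panel`; if simulation keys are
#'   present the corresponding [assay_truth()] table is attached as the
#'   `assay_truth` attribute.
#' @export
read_panel_config <- function(path) {
  blocks <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  if (!nrow(blocks)) stop("empty panel configuration: ", path)
  header <- blocks[1L, , drop = FALSE]
  if (is.null(header$panel_name) || is.na(header$panel_name))
    stop("first block of a panel file must carry panel_name")
  body <- blocks[-1L, , drop = FALSE]
  if (!nrow(body)) stop("panel file has no assay blocks")
  num_cols <- c("predilution_factor", "correction_factor", "a", "d", "c", "b",
                "ct_noise_sd", "sample_logmean", "sample_logsd",
                "qc1_conc", "qc2_conc")
  for (cc in intersect(num_cols, names(body)))
    body[[cc]] <- as.numeric(body[[cc]])
  if ("reassigned" %in% names(body))
    body$reassigned <- as.logical(body$reassigned)
  panel <- pea_panel(header$panel_name[1L], body)
  truth_cols <- c("a", "d", "c", "b", "ct_noise_sd", "sample_logmean",
                  "sample_logsd", "qc1_conc", "qc2_conc")
  if (all(truth_cols %in% names(body)))
    attr(panel, "assay_truth") <-
      assay_truth(cbind(assay_id = body$assay_id, body[truth_cols]))
  panel
}

#' @rdname read_panel_config
#' @export
write_panel_config <- function(panel, path) {
  stopifnot(inherits(panel, "pea_panel"))
  tab <- panel$assays
  truth <- attr(panel, "assay_truth")
  if (!is.null(truth))
    tab <- merge(tab, truth, by = "assay_id", sort = FALSE)
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  header <- data.frame(panel_name = panel$panel_name)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write.dcf(header, con)
  cat("\n", file = con)
  write.dcf(tab, con)
  invisible(path)
}
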