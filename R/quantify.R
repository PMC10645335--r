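#' Quantify samples from NPX through standard curves
#'
#' Inverts each sample NPX through its assay's standard curve and scales to
#' the neat-sample concentration by the panel predilution factor.  Flags:
#' `above_uloq` for NPX beyond the high-concentration asymptote or
#' concentration above ULOQ, `below_lod` below the LOD (or beyond the
#' low-concentration asymptote), `below_lloq` between LOD and LLOQ, else
#' `in_range`.  A non-quantitative curve (no LLOQ) flags every detectable
#' value `below_lloq`.
#'
#' @param npx Long NPX table from [to_npx()] (sample wells are selected by
#'   role unless `roles` says otherwise).
#' @param curves A [standard_curve_set()] covering every assay present.
#' @param panel The [pea_panel()] supplying predilution factors.
#' @param roles Well roles to quantify (default `"sample"`).
#' @return data.frame `plate_id`, `well_id`, `sample_id`, `role`,
#'   `assay_id`, `npx`, `conc` (neat pg/mL, NA when non-invertible), `flag`.
#' @export
quantify_samples <- function(npx, curves, panel, roles = "sample") {
  stopifnot(inherits(curves, "standard_curve_set"))
  npx <- npx[npx$role %in% roles, ]
  miss <- setdiff(unique(npx$assay_id), names(curves))
  if (length(miss))
    stop("no standard curve for assay(s): ", paste(miss, collapse = ", "))
  predil <- stats::setNames(panel$assays$predilution_factor,
                            panel$assays$assay_id)
  out <- lapply(split(npx, npx$assay_id), function(na) {
    aid <- na$assay_id[1L]
    cv <- curves[[aid]]
    inv <- invert_4pl(cv, na$npx)
    side <- attr(inv, "side")
    conc <- as.numeric(inv) * predil[[aid]]
    lod <- if (is.na(cv$lod_conc)) -Inf else cv$lod_conc
    lloq <- if (is.na(cv$lloq_conc)) Inf else cv$lloq_conc
    uloq <- if (is.na(cv$uloq_conc)) Inf else cv$uloq_conc
    flag <- ifelse(is.na(conc),
                   ifelse(side == "high", "above_uloq", "below_lod"),
                   ifelse(conc > uloq, "above_uloq",
                          ifelse(conc < lod, "below_lod",
                                 ifelse(conc < lloq, "below_lloq",
                                        "in_range"))))
    data.frame(plate_id = na$plate_id, well_id = na$well_id,
               sample_id = na$sample_id, role = na$role, assay_id = aid,
               npx = na$npx, conc = conc, flag = flag)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Impute censored concentrations from a lognormal model
#'
#' Fits a lognormal distribution by maximum likelihood treating below-LLOQ
#' (and below-LOD) values as left-censored at the LLOQ and above-ULOQ
#' values as right-censored at the ULOQ, then replaces censored values by
#' draws from the fitted distribution: below-LLOQ draws are truncated above
#' at the minimum observed uncensored value, above-ULOQ draws truncated
#' below at the ULOQ.  Censored fitting uses
#' [fitdistrplus::fitdistcens()]; draws are by inverse-CDF and are
#' seed-deterministic.
#'
#' @param values Concentrations (NA allowed where censored).
#' @param flag Per-value flag from [quantify_samples()]; `in_range` values
#'   are the uncensored observations.
#' @param lloq,uloq Censoring bounds (neat-sample scale).
#' @param seed Integer seed.
#' @return Numeric vector with censored entries imputed; attributes
#'   `meanlog`, `sdlog` (fitted parameters), `n_low`, `n_high`.
#' @export
impute_censored <- function(values, flag, lloq, uloq, seed = 1L) {
  stopifnot(length(values) == length(flag))
  low <- flag %in% c("below_lloq", "below_lod")
  high <- flag == "above_uloq"
  obs <- flag == "in_range"
  if (!any(low) && !any(high)) {
    out <- values
    attr(out, "meanlog") <- NA_real_
    attr(out, "sdlog") <- NA_real_
    attr(out, "n_low") <- 0L
    attr(out, "n_high") <- 0L
    return(out)
  }
  if (sum(obs) < 10L)
    stop("need at least 10 uncensored values to fit the lognormal model")
  if (any(values[obs] <= 0)) stop("uncensored concentrations must be positive")
  cens <- data.frame(
    left = c(values[obs], rep(NA_real_, sum(low)), rep(uloq, sum(high))),
    right = c(values[obs], rep(lloq, sum(low)), rep(NA_real_, sum(high))))
  fit <- fitdistrplus::fitdistcens(cens, "lnorm")
  ml <- fit$estimate[["meanlog"]]
  sl <- fit$estimate[["sdlog"]]
  set.seed(seed)
  out <- values
  if (any(low)) {
    upper <- min(values[obs])      # truncate at the minimum observed value
    p_up <- stats::plnorm(upper, ml, sl)
    u <- stats::runif(sum(low), 0, p_up)
    out[low] <- stats::qlnorm(u, ml, sl)
  }
  if (any(high)) {
    p_lo <- stats::plnorm(uloq, ml, sl)
    u <- stats::runif(sum(high), p_lo, 1)
    out[high] <- stats::qlnorm(u, ml, sl)
  }
  attr(out, "meanlog") <- ml
  attr(out, "sdlog") <- sl
  attr(out, "n_low") <- sum(low)
  attr(out, "n_high") <- sum(high)
  out
}
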