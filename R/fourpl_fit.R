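#' Fit a four-parameter logistic standard curve
#'
#' Least-squares fit of NPX(x) = d + (a-d)/(1 + (x/c)^b) to replicate
#' (concentration, NPX) standard points.  Blank points (x = 0) inform the
#' zero-concentration asymptote: for an increasing concentration-response
#' (b < 0) that is d, for a decreasing one (b > 0) it is a.  Curve
#' orientation is detected from the rank correlation of NPX with log
#' concentration and the sign of b is constrained accordingly; on
#' non-convergence the fit is restarted over |b| in {0.5, 1, 2}.
#' Optimization is Levenberg-Marquardt ([minpack.lm::nls.lm]).
#'
#' @param conc Standard concentrations (in-well scale), `>= 5` distinct
#'   values including 0 for the blank.
#' @param npx Measured NPX, same length.
#' @return Object of class `standard_curve`: list with `assay_id` (NA until
#'   set), parameters `a`, `d`, `c`, `b`, `rss`, `n_points`, and
#'   placeholders `lod_npx`, `lod_conc`, `lloq_conc`, `uloq_conc`,
#'   `quantitative`, `scale`.
#' @param assay_id Optional assay label stored on the curve.
#' @export
fit_4pl <- function(conc, npx, assay_id = NA_character_) {
  ok <- is.finite(conc) & is.finite(npx)
  conc <- conc[ok]; npx <- npx[ok]
  if (any(conc < 0)) stop("negative standard concentrations")
  if (length(unique(conc)) < 5L || !any(conc == 0))
    stop("need at least 5 distinct concentrations including a blank")
  if (length(conc) < 4L) stop("fewer points than parameters")

  pos <- conc > 0
  increasing <- stats::cor(log(conc[pos]), npx[pos],
                           method = "spearman") >= 0
  sgn <- if (increasing) -1 else 1
  a0 <- max(npx)
  d0 <- min(npx)
  blank_mean <- mean(npx[conc == 0])
  if (increasing) d0 <- blank_mean else a0 <- blank_mean
  if (a0 <= d0) { a0 <- max(npx); d0 <- min(npx) }
  # start c where the response crosses the midpoint (a0+d0)/2; the
  # geometric mid-concentration is kept as a fallback start
  grp <- tapply(npx[pos], conc[pos], mean)
  gx <- as.numeric(names(grp))
  c_mid <- gx[which.min(abs(grp - (a0 + d0) / 2))]
  c_geo <- exp(mean(log(range(conc[pos]))))

  resid_fun <- function(p) {
    a <- p[1L]; d <- p[2L]; cc <- exp(p[3L]); b <- p[4L]
    pred <- numeric(length(conc))
    pred[pos] <- fourpl(conc[pos], a, d, cc, b)
    pred[!pos] <- if (b < 0) d else a
    pred - npx
  }
  lower <- c(-Inf, -Inf, -Inf, if (sgn < 0) -10 else 0.05)
  upper <- c(Inf, Inf, Inf, if (sgn < 0) -0.05 else 10)

  best <- NULL
  starts <- expand.grid(b0 = sgn * c(1, 0.5, 2), c0 = c(c_mid, c_geo))
  for (s in seq_len(nrow(starts))) {
    b0 <- starts$b0[s]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(a0, d0, log(starts$c0[s]), b0),
                         fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 * (1 + best$rss))
      best <- list(par = fit$par, rss = rss, info = fit$info)
    if (!is.null(best) && best$rss < 1e-10) break
  }
  if (is.null(best))
    stop("4PL fit failed to converge after multi-start (",
         length(conc), " points)")
  p <- best$par
  curve <- structure(list(
    assay_id = assay_id,
    a = p[1L], d = p[2L], c = exp(p[3L]), b = p[4L],
    rss = best$rss, n_points = length(conc),
    lod_npx = NA_real_, lod_conc = NA_real_,
    lloq_conc = NA_real_, uloq_conc = NA_real_,
    quantitative = NA, scale = 1),
    class = "standard_curve")
  if (curve$a <= curve$d)
    stop("degenerate 4PL fit: upper asymptote does not exceed lower")
  curve
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("4PL standard curve [%s]: a=%.4g d=%.4g c=%.4g b=%.4g (rss %.3g, n=%d)\n",
              x$assay_id, x$a, x$d, x$c, x$b, x$rss, x$n_points))
  cat(sprintf("  LOD %.4g  LLOQ %.4g  ULOQ %.4g  scale %.4g  quantitative: %s\n",
              x$lod_conc, x$lloq_conc, x$uloq_conc, x$scale,
              as.character(x$quantitative)))
  invisible(x)
}

#' Collect standard curves into a set
#'
#' @param curves List of [fit_4pl()] curves.
#' @return `standard_curve_set` (named list) with an `as.data.frame` method.
#' @export
standard_curve_set <- function(curves) {
  stopifnot(all(vapply(curves, inherits, logical(1L), "standard_curve")))
  names(curves) <- vapply(curves, `[[`, character(1L), "assay_id")
  structure(curves, class = "standard_curve_set")
}

#' @export
as.data.frame.standard_curve_set <- function(x, ...) {
  do.call(rbind, lapply(unname(x), function(cv)
    data.frame(assay_id = cv$assay_id, a = cv$a, d = cv$d, c = cv$c,
               b = cv$b, rss = cv$rss, n_points = cv$n_points,
               lod_npx = cv$lod_npx, lod_conc = cv$lod_conc,
               lloq_conc = cv$lloq_conc, uloq_conc = cv$uloq_conc,
               quantitative = cv$quantitative, scale = cv$scale)))
}

#' Invert a standard curve: NPX to concentration
#'
#' x = c * ((a-d)/(npx-d) - 1)^(1/b), the algebraic inverse of the fitted
#' 4PL on its open response interval (d, a).  Values at or beyond the
#' asymptotes are returned as NA (a censoring signal resolved by
#' [quantify_samples()]), with the side recorded in the `"side"` attribute
#' (`"low"`/`"high"` relative to concentration).
#'
#' @param curve A `standard_curve`.
#' @param npx NPX value(s).
#' @return Concentration(s) on the in-well (prediluted) scale.
#' @export
invert_4pl <- function(curve, npx) {
  a <- curve$a; d <- curve$d; cc <- curve$c; b <- curve$b
  inside <- is.finite(npx) & npx > d & npx < a
  x <- rep(NA_real_, length(npx))
  x[inside] <- cc * ((a - d) / (npx[inside] - d) - 1)^(1 / b)
  side <- rep(NA_character_, length(npx))
  # which asymptote maps to high concentration depends on orientation
  hi_npx_is_hi_conc <- b < 0
  side[is.finite(npx) & npx >= a] <- if (hi_npx_is_hi_conc) "high" else "low"
  side[is.finite(npx) & npx <= d] <- if (hi_npx_is_hi_conc) "low" else "high"
  attr(x, "side") <- side
  x
}

#' Determine the limit of detection
#'
#' LOD on the NPX scale is the blank mean plus three sample standard
#' deviations; the concentration LOD is the curve inversion of that NPX,
#' scaled to the neat sample by the predilution factor (NA when the LOD
#' NPX falls outside the invertible response range).
#'
#' @param curve A `standard_curve`.
#' @param blank_npx NPX replicates of negative-control (or blank
#'   calibrator) wells; at least 2.
#' @param predilution Predilution factor for the neat-sample scale.
#' @return The curve with `lod_npx` and `lod_conc` filled in.
#' @export
determine_lod <- function(curve, blank_npx, predilution = 1) {
  blank_npx <- blank_npx[is.finite(blank_npx)]
  if (length(blank_npx) < 2L)
    stop("need at least 2 blank replicates for the LOD")
  curve$lod_npx <- mean(blank_npx) + 3 * stats::sd(blank_npx)
  lod_well <- invert_4pl(curve, curve$lod_npx)
  curve$lod_conc <- as.numeric(lod_well) * predilution
  curve
}

#' Determine LLOQ and ULOQ by the 30% accuracy/precision rule
#'
#' For every nonzero standard concentration the replicates are
#' back-calculated through the curve; accuracy = |mean - nominal|/nominal
#' and precision = SD/mean (sample SD).  A concentration passes when both
#' are <= 0.30 and all its replicates invert.  ULOQ is the largest passing
#' standard and LLOQ the lowest standard of the contiguous passing run
#' containing it; both are reported on the neat-sample scale.  When no
#' standard passes the curve is flagged non-quantitative.
#'
#' @param curve A `standard_curve`.
#' @param conc,npx Replicate standard points (in-well concentration scale).
#' @param predilution Predilution factor for the neat-sample scale.
#' @param threshold Acceptance bound for both accuracy and precision
#'   (inclusive; default 0.30).
#' @return The curve with `lloq_conc`, `uloq_conc`, `quantitative` filled
#'   in, plus a `loq_table` attribute with the per-standard diagnostics.
#' @export
determine_loq <- function(curve, conc, npx, predilution = 1,
                          threshold = 0.30) {
  ok <- is.finite(conc) & conc > 0
  conc <- conc[ok]; npx <- npx[ok]
  nominal <- sort(unique(conc))
  rows <- lapply(nominal, function(x0) {
    reps <- npx[conc == x0]
    if (length(reps) < 2L)
      stop("need >= 2 replicates per standard concentration (", x0, ")")
    back <- as.numeric(invert_4pl(curve, reps))
    if (anyNA(back))
      return(data.frame(nominal = x0, n = length(reps), accuracy = NA_real_,
                        precision = NA_real_, pass = FALSE))
    m <- mean(back)
    data.frame(nominal = x0, n = length(reps),
               accuracy = abs(m - x0) / x0,
               precision = stats::sd(back) / m,
               pass = abs(m - x0) / x0 <= threshold &
                 stats::sd(back) / m <= threshold)
  })
  tab <- do.call(rbind, rows)
  if (!any(tab$pass)) {
    curve$quantitative <- FALSE
    curve$lloq_conc <- NA_real_
    curve$uloq_conc <- NA_real_
  } else {
    hi <- max(which(tab$pass))
    lo <- hi
    while (lo > 1L && tab$pass[lo - 1L]) lo <- lo - 1L
    curve$quantitative <- TRUE
    curve$lloq_conc <- tab$nominal[lo] * predilution
    curve$uloq_conc <- tab$nominal[hi] * predilution
  }
  attr(curve, "loq_table") <- tab
  curve
}

#' Value reassignment against a clinical reference assay
#'
#' Estimates the single multiplicative rescaling s of the standard-curve
#' concentration axis minimizing the squared log2 difference between
#' rescaled quantifications and the reference assay, using paired samples
#' within the quantifiable range: log2 s = mean(log2(reference / pea)).
#' Rescaling the concentration axis maps a 4PL exactly onto a 4PL with
#' c' = s c and a, d, b unchanged, so the refit on rescaled standards is
#' performed in closed form; LOD/LLOQ/ULOQ concentrations scale by s.
#'
#' @param curve A `standard_curve` with LLOQ/ULOQ determined.
#' @param pea_conc Concentrations quantified by the curve (neat scale).
#' @param reference_conc Paired reference-assay concentrations.
#' @param min_pairs Minimum pairs within LOQ (default 10).
#' @return The rescaled curve; the applied scale accumulates in `$scale`.
#' @export
reassign_values <- function(curve, pea_conc, reference_conc,
                            min_pairs = 10L) {
  stopifnot(length(pea_conc) == length(reference_conc))
  ok <- is.finite(pea_conc) & is.finite(reference_conc) &
    pea_conc > 0 & reference_conc > 0
  if (!is.na(curve$lloq_conc))
    ok <- ok & pea_conc >= curve$lloq_conc & pea_conc <= curve$uloq_conc
  n_drop <- sum(!ok)
  if (n_drop)
    message(n_drop, " pair(s) outside the quantifiable range excluded ",
            "from value reassignment")
  if (sum(ok) < min_pairs)
    stop("need at least ", min_pairs,
         " in-range pairs for value reassignment, have ", sum(ok))
  s <- 2^mean(log2(reference_conc[ok] / pea_conc[ok]))
  curve$c <- curve$c * s
  curve$lod_conc <- curve$lod_conc * s
  curve$lloq_conc <- curve$lloq_conc * s
  curve$uloq_conc <- curve$uloq_conc * s
  curve$scale <- curve$scale * s
  attr(curve, "last_scale") <- s
  curve
}
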