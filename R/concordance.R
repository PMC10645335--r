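#' Weighted Harrell's concordance index
#'
#' Fraction of comparable pairs in which the subject with the higher risk
#' score fails earlier.  A pair (i, j) is comparable when subject i has an
#' event and t_i < t_j; ties in score count 1/2.  Pairs are weighted by the
#' product of the two members' sampling weights.
#'
#' @param time Follow-up times.
#' @param event 0/1 event indicator.
#' @param score Risk score (higher = higher predicted risk).
#' @param weights Sampling weights (default 1).
#' @return Scalar concordance in `[0, 1]`.
#' @export
harrells_c <- function(time, event, score, weights = NULL) {
  n <- length(time)
  stopifnot(length(event) == n, length(score) == n)
  if (is.null(weights)) weights <- rep(1, n)
  num <- 0
  den <- 0
  for (i in which(event == 1L)) {
    later <- time > time[i]
    if (!any(later)) next
    wp <- weights[i] * weights[later]
    conc <- (score[i] > score[later]) + 0.5 * (score[i] == score[later])
    num <- num + sum(wp * conc)
    den <- den + sum(wp)
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Fraction of new information
#'
#' FNI = 1 - chi2_A / chi2_B for nested weighted Cox models fitted to the
#' same data, where chi2 is the likelihood-ratio statistic against the null
#' model: the share of the full model's predictive information contributed
#' by the variables absent from the reduced model.  Sampling noise can push
#' the ratio outside `[0, 1]`; values are clipped with a message.
#'
#' @param fit_without Reduced-model [fit_weighted_cox()] (modA), or `NULL`
#'   for the null model (no covariates, chi-square 0, FNI 1).
#' @param fit_with Full-model fit (modB).
#' @return Scalar FNI in `[0, 1]`.
#' @export
fni <- function(fit_without, fit_with) {
  if (fit_with$lr_chisq <= 0)
    stop("full model carries no likelihood-ratio information (chisq = 0)")
  chisq_a <- if (is.null(fit_without)) 0 else fit_without$lr_chisq
  val <- 1 - chisq_a / fit_with$lr_chisq
  if (val < 0 || val > 1) {
    message("FNI ", format(val), " outside [0, 1]; clipped")
    val <- min(max(val, 0), 1)
  }
  val
}

#' Bootstrap optimism-corrected concordance
#'
#' Harrell-Efron internal validation: for each of B bootstrap resamples of
#' subjects (weights carried along), the model is refitted, its apparent
#' concordance on the resample and its concordance on the original data are
#' computed, and the optimism is the mean difference; corrected C =
#' apparent C - optimism.  Resamples without events are redrawn (counted in
#' the `n_redrawn` attribute).  A prespecified score (`refit = FALSE`) has
#' no fitting step, hence zero optimism by definition, and the apparent C
#' is returned unchanged without resampling.
#'
#' @param data data.frame with `time`, `event`, `weight` columns plus
#'   whatever `fitter` needs.
#' @param fitter Function `data -> function(newdata) -> risk score`.
#' @param B Number of bootstrap resamples (default 300).
#' @param seed Integer seed.
#' @param refit Set `FALSE` for a prespecified (non-refit) score.
#' @return List: `apparent`, `optimism`, `corrected`, `B`.
#' @export
bootstrap_optimism <- function(data, fitter, B = 300L, seed = 1L,
                               refit = TRUE) {
  stopifnot(all(c("time", "event", "weight") %in% names(data)), B >= 2L)
  score_fun <- fitter(data)
  apparent <- harrells_c(data$time, data$event, score_fun(data),
                         data$weight)
  if (!refit)
    return(list(apparent = apparent, optimism = 0, corrected = apparent,
                B = 0L))
  set.seed(seed)
  n <- nrow(data)
  opt <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(data$event[idx] == 1L)) break
      n_redrawn <- n_redrawn + 1L
    }
    db <- data[idx, , drop = FALSE]
    fb <- fitter(db)
    c_boot <- harrells_c(db$time, db$event, fb(db), db$weight)
    c_orig <- harrells_c(data$time, data$event, fb(data), data$weight)
    opt[b] <- c_boot - c_orig
  }
  res <- list(apparent = apparent, optimism = mean(opt),
              corrected = apparent - mean(opt), B = B)
  attr(res, "n_redrawn") <- n_redrawn
  res
}
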