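#' Weighted Cox proportional-hazards fit with robust sandwich variance
#'
#' Maximizes the weighted Cox partial likelihood (Breslow handling of tied
#' event times) by damped Newton iterations, for case-cohort and other
#' inverse-probability-weighted designs.  With weights w and linear
#' predictor eta = X beta,
#' \deqn{l(\beta) = \sum_{i: \delta_i = 1} w_i [\eta_i - \log S_0(t_i)],
#'   \quad S_0(t) = \sum_{j: t_j \ge t} w_j e^{\eta_j}.}
#' The robust (sandwich) variance is I^{-1} (sum_i U_i U_i') I^{-1} with
#' per-subject weighted score residuals U_i, matching the
#' infinitesimal-jackknife estimator used for weighted survey designs.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicator (at least one event).
#' @param X Design matrix (columns are covariates; full rank required).
#' @param weights Sampling weights (default 1); must be positive.
#' @param max_iter Newton iteration cap (default 50).
#' @param tol Convergence tolerance on the max absolute score (default
#'   1e-9).
#' @return Object of class `pea_coxfit`: `coefficients`, `var` (inverse
#'   information), `robust_var`, `robust_se`, `loglik_null`, `loglik_full`,
#'   `lr_chisq`, `iter`, `converged`, `n`, `n_events`, `linear_predictor`,
#'   `score_norm`.
#' @export
fit_weighted_cox <- function(time, event, X, weights = NULL,
                             max_iter = 50L, tol = 1e-9) {
  X <- as.matrix(X)
  n <- length(time)
  stopifnot(nrow(X) == n, length(event) == n, all(time > 0))
  event <- as.integer(event)
  if (!any(event == 1L)) stop("need at least one event")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0) || any(!is.finite(weights)))
    stop("weights must be positive and finite")
  p <- ncol(X)
  if (p < 1L) stop("design matrix has no columns")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(scale(X, center = TRUE, scale = FALSE))
  if (qrX$rank < p)
    stop("design is rank deficient; collinear columns: ",
         paste(colnames(X)[-qrX$pivot[seq_len(qrX$rank)]], collapse = ", "))

  ord <- order(time)
  ts <- time[ord]; ev <- event[ord]; w <- weights[ord]
  Xs <- X[ord, , drop = FALSE]
  first_of_tie <- match(ts, ts)     # index of first row sharing each time
  drows <- which(ev == 1L)
  revcum_mat <- function(m) {
    m <- m[n:1, , drop = FALSE]
    m <- apply(m, 2L, cumsum)
    if (!is.matrix(m)) m <- matrix(m, nrow = n)
    m[n:1, , drop = FALSE]
  }
  # half-vectorized cross products for the S2 cumulative sums
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  XX <- Xs[, pairs[, 1L], drop = FALSE] * Xs[, pairs[, 2L], drop = FALSE]
  unvech <- function(v) {
    m <- matrix(0, p, p)
    m[cbind(pairs[, 1L], pairs[, 2L])] <- v
    m[cbind(pairs[, 2L], pairs[, 1L])] <- v
    m
  }

  loglik_of <- function(beta) {
    eta <- drop(Xs %*% beta)
    e <- w * exp(eta)
    S0 <- rev(cumsum(rev(e)))[first_of_tie]
    sum(w[drows] * (eta[drows] - log(S0[drows])))
  }

  lik_parts <- function(beta) {
    eta <- drop(Xs %*% beta)
    e <- w * exp(eta)
    S0 <- rev(cumsum(rev(e)))[first_of_tie]
    S1 <- revcum_mat(Xs * e)[first_of_tie, , drop = FALSE]
    mu <- S1[drows, , drop = FALSE] / S0[drows]
    ll <- sum(w[drows] * (eta[drows] - log(S0[drows])))
    g <- colSums(w[drows] * (Xs[drows, , drop = FALSE] - mu))
    # information = sum over deaths of w_d (S2/S0 - mu mu')
    S2d <- revcum_mat(XX * e)[first_of_tie[drows], , drop = FALSE]
    vech_sum <- colSums(S2d * (w[drows] / S0[drows]))
    I <- unvech(vech_sum) - crossprod(mu, mu * w[drows])
    list(ll = ll, g = g, H = -I, e = e, S0 = S0, mu = mu, drows = drows,
         eta = eta)
  }

  beta <- rep(0, p)
  parts <- lik_parts(beta)
  ll0 <- parts$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(parts$g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-parts$H, parts$g), error = function(e)
      stop("singular information matrix at iteration ", iter,
           " (possible separation); last score norm ",
           format(max(abs(parts$g)))))
    fac <- 1
    repeat {
      cand <- beta + fac * step
      ll_cand <- loglik_of(cand)
      if (is.finite(ll_cand) && ll_cand >= parts$ll - 1e-12)
        break
      fac <- fac / 2
      if (fac < 1e-10)
        stop("step halving failed; last score norm ",
             format(max(abs(parts$g))))
    }
    beta <- cand
    parts <- lik_parts(beta)
  }
  if (!converged && max(abs(parts$g)) < tol) converged <- TRUE
  if (!converged)
    stop("Newton iterations did not converge after ", max_iter,
         " iterations; last score norm ", format(max(abs(parts$g))))

  info <- -parts$H
  V <- solve(info)
  # weighted score residuals
  drows <- parts$drows
  dt <- ts[drows]
  aK <- w[drows] / parts$S0[drows]            # per-death w_d / S0
  cumA <- cumsum(aK)
  cumB <- apply(parts$mu * aK, 2L, cumsum)
  idx <- findInterval(ts, dt)                  # deaths with t_k <= t_i
  A <- c(0, cumA)[idx + 1L]
  B <- rbind(0, cumB)[idx + 1L, , drop = FALSE]
  U <- -parts$e * (Xs * A - B)
  mu_at <- matrix(0, n, p)
  mu_at[drows, ] <- parts$mu
  U[drows, ] <- U[drows, ] + w[drows] * (Xs[drows, , drop = FALSE] -
                                           parts$mu)
  robust <- V %*% crossprod(U) %*% V

  fit <- structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    var = V, robust_var = robust,
    robust_se = stats::setNames(sqrt(diag(robust)), colnames(X)),
    loglik_null = ll0, loglik_full = parts$ll,
    lr_chisq = 2 * (parts$ll - ll0),
    iter = iter, converged = converged,
    n = n, n_events = sum(ev),
    linear_predictor = drop(X %*% beta),
    score_norm = max(abs(parts$g))),
    class = "pea_coxfit")
  fit
}

#' @export
print.pea_coxfit <- function(x, ...) {
  cat(sprintf("Weighted Cox fit: n=%d, events=%d, LR chisq=%.3f (%d iter)\n",
              x$n, x$n_events, x$lr_chisq, x$iter))
  print(data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                   robust_se = x$robust_se, check.names = FALSE))
  invisible(x)
}

#' Hazard ratio for the third versus first quartile of a covariate
#'
#' Evaluates the fitted (possibly spline) contribution of one covariate at
#' its 75th and 25th percentiles; HR = exp(eta(Q3) - eta(Q1)) with a
#' delta-method confidence interval from the robust covariance.
#'
#' @param fit A [fit_weighted_cox()] result.
#' @param basis An [rcs_basis()] for the covariate (its column names must
#'   match coefficients of `fit`), or a single coefficient name for a
#'   linear term.
#' @param x Covariate values defining the quartiles.
#' @param level Confidence level (default 0.95).
#' @return One-row data.frame: `hr`, `lower`, `upper`, `log_hr`,
#'   `se_log_hr`, `q1`, `q3`.
#' @export
hr_q3_vs_q1 <- function(fit, basis, x, level = 0.95) {
  q <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  if (inherits(basis, "rcs_basis")) {
    z3 <- predict(basis, q[2L]); z1 <- predict(basis, q[1L])
    dz <- drop(z3 - z1)
    names(dz) <- colnames(z3)
  } else {
    dz <- stats::setNames(q[2L] - q[1L], basis)
  }
  miss <- setdiff(names(dz), names(fit$coefficients))
  if (length(miss))
    stop("fit lacks coefficient(s): ", paste(miss, collapse = ", "))
  v <- rep(0, length(fit$coefficients))
  names(v) <- names(fit$coefficients)
  v[names(dz)] <- dz
  est <- sum(v * fit$coefficients)
  se <- sqrt(drop(t(v) %*% fit$robust_var %*% v))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(hr = exp(est), lower = exp(est - zq * se),
             upper = exp(est + zq * se), log_hr = est, se_log_hr = se,
             q1 = q[1L], q3 = q[2L])
}
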