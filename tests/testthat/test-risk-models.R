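test_that("restricted cubic spline basis has the defining properties", {
  set.seed(1)
  x <- rnorm(300)
  bs <- rcs_basis(x, name = "z")
  k <- bs$knots
  expect_equal(unname(k), unname(quantile(x, c(.05, .35, .65, .95), type = 7)))
  # nonlinear terms vanish at and below the first knot
  below <- predict(bs, seq(min(x) - 1, k[1], length.out = 20))
  expect_equal(unname(below[, 2:3]), matrix(0, 20, 2))
  # linear beyond the last knot: vanishing second differences
  grid <- seq(k[4], k[4] + 5, length.out = 50)
  m <- predict(bs, grid)
  for (j in 1:3) expect_equal(diff(m[, j], differences = 2),
                              rep(0, 48), tolerance = 1e-10)
  # direct truncated-power evaluation on a grid
  g <- seq(min(x), max(x), length.out = 200)
  got <- predict(bs, g)
  cub <- function(u, t) pmax(u - t, 0)^3
  for (j in 1:2) {
    want <- (cub(g, k[j]) - cub(g, k[3]) * (k[4] - k[j]) / (k[4] - k[3]) +
               cub(g, k[4]) * (k[3] - k[j]) / (k[4] - k[3])) / (k[4] - k[1])^2
    expect_equal(unname(got[, j + 1]), want)
  }
  expect_error(rcs_basis(x, knots = c(1, 1, 2, 3)), "distinct")
})

test_that("weighted Cox matches coxph on coefficients, robust SE and LR", {
  skip_if_not_installed("survival")
  set.seed(42)
  n <- 250
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  t_ev <- rexp(n, 0.1 * exp(0.5 * x1 - 0.3 * x2))
  time <- pmin(t_ev, 5); event <- as.integer(t_ev <= 5)
  w <- runif(n, 1, 3)
  X <- cbind(x1 = x1, x2 = x2)
  fit <- fit_weighted_cox(time, event, X, w)
  cf <- survival::coxph(survival::Surv(time, event) ~ x1 + x2, weights = w,
                        robust = TRUE, ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(cf)), tolerance = 1e-7)
  expect_equal(unname(fit$robust_se), unname(sqrt(diag(cf$var))),
               tolerance = 1e-6)
  expect_equal(fit$lr_chisq, 2 * diff(cf$loglik)[[1]], tolerance = 1e-7)
  expect_lt(fit$score_norm, 1e-8)
  # heavy ties keep the agreement (Breslow)
  time2 <- pmax(round(time, 0), 1)
  fit2 <- fit_weighted_cox(time2, event, X, w)
  cf2 <- survival::coxph(survival::Surv(time2, event) ~ x1 + x2,
                         weights = w, robust = TRUE, ties = "breslow")
  expect_equal(unname(fit2$coefficients), unname(coef(cf2)),
               tolerance = 1e-7)
  expect_equal(unname(fit2$robust_se), unname(sqrt(diag(cf2$var))),
               tolerance = 1e-6)
})

test_that("equal weights reproduce the unweighted fit exactly", {
  set.seed(3)
  n <- 120
  x <- rnorm(n)
  t_ev <- rexp(n, 0.2 * exp(0.4 * x))
  time <- pmin(t_ev, 4); event <- as.integer(t_ev <= 4)
  f1 <- fit_weighted_cox(time, event, cbind(x = x))
  f2 <- fit_weighted_cox(time, event, cbind(x = x), weights = rep(2, n))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
})

test_that("tiny-n coefficient matches a grid-search likelihood maximizer", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 1, 0, 1, 0, 1, 0, 0)
  w <- c(1, 2, 1, 1, 2, 1, 1, 1)
  fit <- fit_weighted_cox(time, event, cbind(x = x), w)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, brute_force_cox_loglik, numeric(1),
               time = time, event = event, x = x, w = w)
  expect_equal(unname(fit$coefficients), grid[which.max(ll)],
               tolerance = 1e-4)
})

test_that("LR chi-square is invariant to affine rescaling of covariates", {
  set.seed(8)
  n <- 150
  x <- rnorm(n)
  t_ev <- rexp(n, 0.15 * exp(0.5 * x))
  time <- pmin(t_ev, 4); event <- as.integer(t_ev <= 4)
  f1 <- fit_weighted_cox(time, event, cbind(x = x))
  f2 <- fit_weighted_cox(time, event, cbind(x = 10 * x + 3))
  expect_equal(f1$lr_chisq, f2$lr_chisq, tolerance = 1e-7)
})

test_that("rank-deficient designs are rejected by name", {
  set.seed(2)
  n <- 60
  x <- rnorm(n)
  t_ev <- rexp(n, 0.2)
  time <- pmin(t_ev, 4); event <- as.integer(t_ev <= 4)
  expect_error(fit_weighted_cox(time, event,
                                cbind(a = x, b = 2 * x)),
               "rank deficient")
})

test_that("case-cohort weighting recovers the full-cohort estimate", {
  ct <- cohort_truth(n_cohort = 3000, log_hr = c(biomarker = 0.5))
  cc <- simulate_case_cohort(ct, seed = 9)
  full <- attr(cc, "full_cohort")
  f_full <- fit_weighted_cox(full$time, full$event,
                             cbind(biomarker = full$biomarker))
  f_cc <- fit_weighted_cox(cc$time, cc$event,
                           cbind(biomarker = cc$biomarker), cc$weight)
  expect_equal(unname(f_cc$coefficients), unname(f_full$coefficients),
               tolerance = 3 * f_cc$robust_se)
  ci <- f_cc$coefficients + c(-1.96, 1.96) * f_cc$robust_se
  expect_true(ci[1] < 0.5 && 0.5 < ci[2])
})

test_that("concordance equals the brute-force pair enumeration", {
  # hand-worked example: times 1..4 all events, scores 4,3,1,2
  expect_equal(harrells_c(1:4, rep(1L, 4), c(4, 3, 1, 2)), 5 / 6)
  # perfect ranking, no censoring
  set.seed(4)
  tt <- sort(rexp(20))
  expect_equal(harrells_c(tt, rep(1L, 20), rev(seq_along(tt))), 1)
  # random censored weighted data with score ties
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:50, 1)
    time <- round(rexp(n, 0.5), 1) + 0.1
    event <- rbinom(n, 1, 0.6)
    score <- sample(1:5, n, replace = TRUE)
    w <- runif(n, 0.5, 3)
    if (!any(event == 1) || all(time[event == 1] >= max(time))) next
    expect_equal(harrells_c(time, event, score, w),
                 brute_force_c(time, event, score, w))
  }
})

test_that("quartile hazard ratios follow the closed form for linear effects", {
  set.seed(6)
  n <- 400
  x <- rnorm(n)
  t_ev <- rexp(n, 0.1 * exp(0.4 * x))
  time <- pmin(t_ev, 5); event <- as.integer(t_ev <= 5)
  fit <- fit_weighted_cox(time, event, cbind(x = x))
  hr <- hr_q3_vs_q1(fit, "x", x)
  q <- quantile(x, c(.25, .75), type = 7)
  expect_equal(hr$hr, exp(unname(fit$coefficients["x"] * (q[2] - q[1]))))
  expect_true(hr$lower < hr$hr && hr$hr < hr$upper)
  # beta = 0 gives HR 1
  fit0 <- fit
  fit0$coefficients["x"] <- 0
  expect_equal(hr_q3_vs_q1(fit0, "x", x)$hr, 1)
  # spline fit on log-linear data agrees with the closed form
  bs <- rcs_basis(x, name = "x")
  fit_s <- fit_weighted_cox(time, event, bs$design)
  hr_s <- hr_q3_vs_q1(fit_s, bs, x)
  expect_equal(log(hr_s$hr), unname(0.4 * (q[2] - q[1])), tolerance = 0.25)
})

test_that("FNI is 0 for identical models, 1 against a null reduced model", {
  set.seed(11)
  n <- 300
  x <- rnorm(n); z <- rnorm(n)
  t_ev <- rexp(n, 0.1 * exp(0.6 * x))
  time <- pmin(t_ev, 5); event <- as.integer(t_ev <= 5)
  fit_x <- fit_weighted_cox(time, event, cbind(x = x))
  fit_xz <- fit_weighted_cox(time, event, cbind(x = x, z = z))
  expect_equal(fni(fit_x, fit_x), 0)
  # a covariate independent of the outcome adds almost no information
  expect_lt(fni(fit_x, fit_xz), 0.1)
  # reduced model with no information: FNI of the full model is ~1
  null_like <- fit_weighted_cox(time, event, cbind(z = z))
  expect_gt(fni(null_like, fit_xz), 0.8)
  bad <- fit_x; bad$lr_chisq <- 0
  expect_error(fni(fit_x, bad), "chisq = 0")
})

test_that("mean FNI of an uninformative biomarker shrinks with sample size", {
  mean_fni <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      x <- rnorm(n); z <- rnorm(n)
      t_ev <- rexp(n, 0.1 * exp(0.6 * x))
      time <- pmin(t_ev, 5); event <- as.integer(t_ev <= 5)
      fa <- fit_weighted_cox(time, event, cbind(x = x))
      fb <- fit_weighted_cox(time, event, cbind(x = x, z = z))
      fni(fa, fb)
    }, numeric(1)))
  }
  small <- mean_fni(60, 1:15)
  large <- mean_fni(600, 1:15)
  expect_lt(large, small)
  expect_lt(large, 0.05)
})

test_that("bootstrap optimism is zero for a prespecified score and positive for overfitting", {
  set.seed(19)
  n <- 80
  dat <- data.frame(time = pmin(rexp(n, 0.3), 4))
  dat$event <- as.integer(dat$time < 4)
  dat$weight <- 1
  dat$risk <- rnorm(n)
  fixed_fitter <- function(d) function(newdata) newdata$risk
  r <- bootstrap_optimism(dat, fixed_fitter, B = 50, seed = 1,
                          refit = FALSE)
  expect_identical(r$optimism, 0)
  expect_identical(r$corrected, r$apparent)

  # many noise covariates on a small sample: corrected < apparent
  p <- 10
  noise <- matrix(rnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("n", 1:p)))
  dat2 <- cbind(dat[c("time", "event", "weight")], noise)
  overfitter <- function(d) {
    f <- fit_weighted_cox(d$time, d$event,
                          as.matrix(d[paste0("n", 1:p)]), d$weight)
    function(newdata)
      drop(as.matrix(newdata[paste0("n", 1:p)]) %*% f$coefficients)
  }
  r2 <- bootstrap_optimism(dat2, overfitter, B = 40, seed = 2)
  expect_gt(r2$optimism, 0)
  expect_lt(r2$corrected, r2$apparent)
})

test_that("model comparison ranks an informative biomarker model above clinical-only", {
  ct <- cohort_truth(n_cohort = 2500, baseline_hazard = 0.05,
                     log_hr = c(age = 0.03, biomarker = 0.8))
  cc <- simulate_case_cohort(ct, seed = 23)
  specs <- list(clinical = c("age", "sex", "bmi"),
                biomarker = c("age", "sex", "bmi", "biomarker"))
  cmp <- compare_models(cc, specs, n_spline = 1, B_optimism = 25,
                        B_pairwise = 200, seed = 3)
  tab <- cmp$models
  expect_gt(tab$c_index[tab$model == "biomarker"],
            tab$c_index[tab$model == "clinical"])
  pw <- cmp$pairwise
  delta <- pw$delta_c[pw$model_a == "clinical" & pw$model_b == "biomarker"]
  expect_lt(pw$upper[pw$model_a == "clinical" & pw$model_b == "biomarker"], 0)
  # the biomarker carries most of the new information in its model
  fni_bio <- cmp$fni$fni[cmp$fni$model == "biomarker" &
                           cmp$fni$variable == "biomarker"]
  expect_gt(fni_bio, 0.3)
  # corrected C does not exceed apparent C materially
  expect_lt(tab$c_index_corrected[2], tab$c_index[2] + 0.02)
})

test_that("model comparison is invariant to subject order and to identical specs", {
  ct <- cohort_truth(n_cohort = 1500, log_hr = c(biomarker = 0.5))
  cc <- simulate_case_cohort(ct, seed = 29)
  specs <- list(m1 = c("age", "biomarker"), m2 = c("age", "biomarker"))
  cmp <- compare_models(cc, specs, n_spline = 0, B_optimism = 0,
                        B_pairwise = 100, seed = 5)
  expect_equal(cmp$models$c_index[1], cmp$models$c_index[2])
  expect_equal(cmp$pairwise$delta_c, 0)
  perm <- cc[sample.int(nrow(cc)), ]
  cmp2 <- compare_models(perm, specs["m1"], n_spline = 0, B_optimism = 0,
                         B_pairwise = 0, seed = 5)
  expect_equal(cmp2$models$c_index, cmp$models$c_index[1])
})
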