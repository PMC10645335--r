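#' Cohort-level simulation truth
#'
#' Proportional-hazards generative model for a case-cohort design:
#' exponential event times with rate `baseline_hazard * exp(eta)` where
#' eta is the log-linear combination of (centered) covariates,
#' administrative censoring at `censor_time`, and sampling of all cases
#' plus approximately `noncase_multiple` times as many non-cases.
#' Defaults emulate a three-year chronic coronary syndrome follow-up with
#' roughly a 10% event rate.
#'
#' @param n_cohort Full-cohort size.
#' @param baseline_hazard Events per unit time at eta = 0.
#' @param log_hr Named vector of log hazard ratios per covariate.
#' @param censor_time Administrative censoring horizon.
#' @param noncase_multiple Sampled non-cases per case (about 2).
#' @return List of class `cohort_truth`.
#' @export
cohort_truth <- function(n_cohort = 5000L, baseline_hazard = 0.036,
                         log_hr = c(biomarker = 0.5), censor_time = 3,
                         noncase_multiple = 2) {
  stopifnot(n_cohort > 0L, baseline_hazard > 0, censor_time > 0,
            noncase_multiple > 0)
  structure(list(n_cohort = as.integer(n_cohort),
                 baseline_hazard = baseline_hazard,
                 log_hr = log_hr, censor_time = censor_time,
                 noncase_multiple = noncase_multiple),
            class = "cohort_truth")
}

#' Default covariate distributions for the cohort generator
#'
#' Clinical covariates (age, sex, BMI, smoking, diabetes, hypertension)
#' plus standard-normal log2-scale biomarkers; each entry is
#' `list(dist = "normal"|"binary"|"lognormal", mean/sd or p)`.
#'
#' @param biomarkers Character vector of biomarker covariate names to add
#'   as standard normals (log2-scale NPX-like values).
#' @return Named list of distribution specs.
#' @export
default_covariate_spec <- function(biomarkers = "biomarker") {
  spec <- list(
    age = list(dist = "normal", mean = 64, sd = 9),
    sex = list(dist = "binary", p = 0.2),
    bmi = list(dist = "normal", mean = 28, sd = 4.5),
    smoking = list(dist = "binary", p = 0.2),
    diabetes = list(dist = "binary", p = 0.35),
    hypertension = list(dist = "binary", p = 0.7))
  for (b in biomarkers)
    spec[[b]] <- list(dist = "normal", mean = 0, sd = 1)
  spec
}

draw_covariate <- function(spec, n) {
  switch(spec$dist,
         normal = stats::rnorm(n, spec$mean, spec$sd),
         binary = stats::rbinom(n, 1L, spec$p),
         lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
         stop("unknown covariate distribution: ", spec$dist))
}

covariate_center <- function(spec) {
  switch(spec$dist,
         normal = spec$mean,
         binary = spec$p,
         lognormal = exp(spec$meanlog + spec$sdlog^2 / 2),
         0)
}

#' Simulate a case-cohort survival study
#'
#' Draws the full cohort under the proportional-hazards truth, keeps all
#' cases, and samples `round(noncase_multiple * n_cases)` non-cases at
#' random.  Sampling weights are Barlow-style: 1 for cases, the inverse
#' non-case sampling fraction for sampled non-cases, so a weighted Cox fit
#' on the sample estimates the full-cohort model.
#'
#' @param truth A [cohort_truth()].
#' @param covariate_spec Distribution list as from
#'   [default_covariate_spec()]; must cover every name in `truth$log_hr`.
#' @param seed Integer seed.
#' @return data.frame `subject_id`, `time`, `event`, `in_subcohort`,
#'   `weight`, covariates; the full simulated cohort is attached as the
#'   `full_cohort` attribute and the non-case sampling fraction as
#'   `sampling_fraction`.
#' @export
simulate_case_cohort <- function(truth, covariate_spec =
                                   default_covariate_spec(names(truth$log_hr)),
                                 seed = 1L) {
  stopifnot(inherits(truth, "cohort_truth"))
  miss <- setdiff(names(truth$log_hr), names(covariate_spec))
  if (length(miss))
    stop("covariate_spec lacks: ", paste(miss, collapse = ", "))
  set.seed(seed)
  n <- truth$n_cohort
  X <- as.data.frame(lapply(covariate_spec, draw_covariate, n = n))
  eta <- rep(0, n)
  for (v in names(truth$log_hr))
    eta <- eta + truth$log_hr[[v]] *
      (X[[v]] - covariate_center(covariate_spec[[v]]))
  t_event <- stats::rexp(n, truth$baseline_hazard * exp(eta))
  event <- as.integer(t_event <= truth$censor_time)
  full <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                     time = pmin(t_event, truth$censor_time),
                     event = event, X)
  cases <- which(event == 1L)
  noncases <- which(event == 0L)
  if (!length(cases))
    stop("no cases simulated; increase n_cohort or baseline_hazard")
  m <- min(length(noncases), round(truth$noncase_multiple * length(cases)))
  sel_nc <- sort(sample(noncases, m))
  f <- m / length(noncases)
  samp <- full[c(cases, sel_nc), , drop = FALSE]
  samp$in_subcohort <- c(rep(FALSE, length(cases)), rep(TRUE, m))
  samp$weight <- ifelse(samp$event == 1L, 1, 1 / f)
  samp <- samp[order(samp$subject_id), ,
               drop = FALSE][, c("subject_id", "time", "event",
                                 "in_subcohort", "weight",
                                 names(covariate_spec))]
  rownames(samp) <- NULL
  attr(samp, "full_cohort") <- full
  attr(samp, "sampling_fraction") <- f
  attr(samp, "seed") <- seed
  samp
}

#' Derive Barlow-style case-cohort weights
#'
#' Cases get weight 1; non-cases in the sampled subcohort get the inverse
#' of the non-case sampling fraction, which requires the full-cohort
#' non-case count.
#'
#' @param data Survival table with `event` and `in_subcohort` columns.
#' @param n_noncases_cohort Number of non-cases in the full cohort.
#' @return Numeric weight vector.
#' @export
derive_case_cohort_weights <- function(data, n_noncases_cohort) {
  m <- sum(data$in_subcohort & data$event == 0L)
  if (m == 0L) stop("no sampled non-cases to weight")
  f <- m / n_noncases_cohort
  ifelse(data$event == 1L, 1, 1 / f)
}
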