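---
title: "Methods: quantitative PEA processing and case-cohort risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative PEA processing and case-cohort risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peaquant)
```

# Scope

`peaquant` implements the computational stack behind a quantitative
multiplex Proximity Extension Assay (PEA): plate processing from raw qPCR
cycle thresholds (Ct) to absolute concentrations, the analytical-validation
metric suite, and a case-cohort prognostic-modelling layer.  Because
clinical plasma datasets of this kind are not public, the package carries a
first-class synthetic-data layer whose generative model matches the
assumptions of every downstream stage; all tests and the acceptance script
run end to end on generated data.

# Normalization model

A PEA well reports one Ct per assay plus the Ct of an internal extension
control.  Three steps take Ct to Normalized Protein eXpression (NPX, log2
scale):

1. **Within-run**: dCt = Ct − Ct(extension control), removing per-well
   technical variation (anything that shifts all assays of a well by a
   constant cancels exactly).
2. **Between-run**: each plate carries triplicate High/Middle/Low/Blank
   calibrators.  Per assay, the median of each non-blank triplicate is
   taken and the mean of the three medians (`dct_cal`) is subtracted:
   ddCt = dCt − dct_cal.  A plate-wide additive shift (a run offset)
   affects samples and calibrators alike and cancels.
3. **Correction factor**: NPX = cf − ddCt.  The sign is chosen so that more
   protein (lower Ct) gives higher NPX; with a blank-anchored correction
   factor the background sits near zero.

**Numerical detail.** ddCt is evaluated as the mean of the three per-level
differences `dct − median(level)` rather than `dct − mean(medians)`.  The
forms are algebraically identical, but the difference-first form makes the
run-offset cancellation *bit-exact* in floating point: the shift cancels
inside each subtraction before any aggregation rounds.  The cancellation
test uses shifts exactly representable at the Ct magnitude (e.g. 1.0, 0.5,
0.25 cycles); arbitrary real shifts cancel to the last unit of precision.

# Calibration and quantification

The concentration–response is the four-parameter logistic (4PL)

$$\mathrm{NPX}(x) = d + \frac{a - d}{1 + (x/c)^b},$$

with upper plateau $a$, lower plateau $d$, inflection $c$ and slope $b$.
In this parameterization an *increasing* immunoassay response corresponds
to $b < 0$ (at $x = 0$ the term $(x/c)^b$ diverges and the response sits at
$d$).  `fit_4pl()` detects orientation from the rank correlation of NPX
with log concentration and constrains the sign of $b$ accordingly, so
decreasing curves ($b > 0$) are fitted equally well.

* **Fitting**: Levenberg–Marquardt least squares on all replicate points,
  with blanks pinned at the zero-concentration asymptote.  Starts:
  $d_0$ = blank mean, $a_0$ = max NPX, $c_0$ at the concentration whose
  mean response is closest to the midpoint (with the geometric
  mid-concentration as a second start), $|b_0| \in \{1, 0.5, 2\}$.  The
  multi-start matters: a single geometric-mid start can land in a
  degenerate shallow-slope basin.  `c` is optimized on the log scale.
* **Inversion**: $x = c\,((a-d)/(\mathrm{npx}-d) - 1)^{1/b}$, the exact
  algebraic inverse; round trips are accurate to better than $10^{-9}$
  relative across the open response interval.
* **LOD**: blank mean + 3 sample SD on the NPX scale (negative-control
  wells preferred, blank calibrators accepted), inverted to concentration.
* **LLOQ/ULOQ**: per standard concentration, replicates are
  back-calculated; accuracy = |mean − nominal|/nominal and precision =
  SD/mean must both be ≤ 0.30 (inclusive).  The limits live on the
  standard-concentration grid — no interpolation between standards, since
  the rule is defined on curve data points.  ULOQ is the largest passing
  standard; LLOQ is the bottom of the contiguous passing run containing
  ULOQ.  If nothing passes the curve is flagged non-quantitative — the
  behaviour of an assay whose inflection sits far above circulating
  levels, as for a prediluted cardiac troponin.
* **Predilution**: samples are prediluted ten-fold; curves are fitted on
  the in-well scale and all reported concentrations (and limits) are
  multiplied back to the neat-sample scale.
* **Value reassignment**: for assays bridged to a clinical reference
  method, a single multiplicative rescaling of the concentration axis is
  estimated from paired in-range samples by minimizing the squared log2
  difference, giving $\log_2 s = \overline{\log_2(\mathrm{ref}/\mathrm{pea})}$.
  Rescaling the axis maps a 4PL exactly onto a 4PL with $c' = s\,c$ and
  $a, d, b$ unchanged, so the refit on rescaled standards is done in
  closed form and LOD/LLOQ/ULOQ scale by $s$.  Applying the procedure a
  second time yields $s = 1$.
* **Censored imputation**: concentrations outside the quantifiable range
  are treated as left-censored at LLOQ / right-censored at ULOQ; a
  lognormal model is fitted by censored maximum likelihood
  (`fitdistrplus::fitdistcens`) and censored values are drawn from the
  fitted distribution truncated above at the minimum observed uncensored
  value (below LLOQ) or below at ULOQ (above ULOQ), by inverse-CDF so the
  draws are seed-deterministic.

# Analytical validation metrics

* **Linearity of dilution**: a high and a low native sample are mixed at
  five equally spaced ratios; the theoretical concentration of a mixture
  is the ratio-weighted mean of the *measured* endpoints, and the
  relative error is (measured − theoretical)/theoretical.  The signed mean
  and the maximum absolute error are reported.
* **QC accuracy and precision**: accuracy = mean(replicates)/reference ×
  100, CV = sample SD/mean × 100; acceptance is accuracy within [75, 125]%.
  Replicates pool per chip (6 = 2 plates × 3) when plate pairs are
  declared, else per plate (3).
* **Dynamic range**: per assay, the fractions of samples below LLOQ,
  above ULOQ, and in range (summing to one).
* **Method comparison**: Spearman rank correlation (average ranks on
  ties), squared Pearson correlation of log2 values, and Bland–Altman mean
  ± 1.96 SD limits of the paired log2 differences.  1.96 is the
  conventional 95% limit multiplier.

# Survival modelling layer

* **Weighted Cox**: the partial likelihood with Breslow tie handling and
  per-subject sampling weights is maximized by damped Newton iterations
  (step halving on non-increase, convergence at max |score| < 1e−9, cap 50
  iterations).  Gradient, Hessian and the robust (sandwich) variance from
  weighted score residuals are computed in closed form with cumulative-sum
  risk-set algebra; the fit matches `survival::coxph(..., robust = TRUE,
  ties = "breslow")` to machine precision in tests, which serve as an
  independent cross-check rather than the implementation.
* **Case-cohort weights**: all cases weight 1; sampled non-cases the
  inverse non-case sampling fraction (Barlow).  Robust standard errors
  give close-to-nominal CI coverage in the package's recovery simulations.
* **Restricted cubic splines**: 4 knots at the 5th/35th/65th/95th
  percentiles, truncated-power basis normalized by the squared
  boundary-knot span; linear beyond the boundary knots, nonlinear terms
  zero at and below the first knot.
* **Spline prioritization**: models first fit all continuous covariates as
  splines, rank them by the likelihood-ratio χ² of dropping each, and keep
  splines only for the top K (default 5), the rest becoming linear.  This
  caps degrees of freedom and hence overfitting; K is configurable because
  no principled universal value exists.
* **Quartile hazard ratios**: HR = exp(η(Q3) − η(Q1)) of the fitted
  (possibly spline) covariate contribution, with a delta-method CI from
  the robust covariance.
* **Harrell's C**: weighted fraction of comparable pairs (event before a
  longer follow-up) ranked correctly, score ties counting ½, pairs
  weighted by the product of member weights.  Verified against a
  brute-force double loop.
* **FNI**: 1 − χ²(reduced)/χ²(full) for nested fits on identical data;
  values nudged outside [0, 1] by sampling noise are clipped with a
  message.  `fni(NULL, fit)` treats the reduced model as the null model.
* **Bootstrap optimism**: Harrell–Efron internal validation (default 300
  resamples): refit on the resample, C(resample) − C(original data)
  averaged, subtracted from the apparent C.  Resamples without events are
  redrawn.  Inside `compare_models()` the resample refits the *selected
  model form* (spline variables fixed to the apparent selection, knots and
  coefficients re-estimated), the standard practice for validating a final
  model.  A prespecified score involves no fitting, so its optimism is
  zero by definition (`refit = FALSE` returns the apparent C unchanged);
  literally resampling-and-rescoring a frozen model would instead produce
  a mean-zero random quantity and estimate the same thing with extra
  noise.
* **Pairwise model comparison**: differences in C between model
  configurations are assessed by a paired bootstrap over subjects with the
  fitted risk scores held fixed (default 2000 resamples), a deliberately
  assumption-light replacement for closed-form correlated-C variance
  estimators.

# Synthetic-data generators

`simulate_plates()` mirrors the measurement process: per well a base Ct
(extension control) carrying the run offset and per-well technical shift,
plus a per-assay dCt that encodes the 4PL response at the in-well
concentration, plus Gaussian Ct noise.  Calibrator truths sit at 16c, c,
c/16 (High/Middle/Low) and 0 (Blank) — spanning the dynamic region, since
no canonical placement exists; they are configurable.  The per-assay
correction factor is defined as the mean calibrator response under the
truth, which makes noiseless normalized NPX equal the generative
concentration–response exactly — the property the end-to-end identity test
exploits.  Default Cts land in the 16–31 cycle range typical of
microfluidic qPCR.  The default 21-assay truth spans sub-pg/mL to
10⁵ pg/mL abundances and includes one deliberately desensitized troponin
assay whose samples fall below the quantifiable range after ten-fold
predilution.

`simulate_case_cohort()` draws exponential event times under a
proportional-hazards truth with centered covariate effects, administers
censoring at a fixed horizon (default 3 years, baseline hazard 0.036/year,
about a 10% event fraction — the regime of a chronic coronary syndrome
cohort), keeps all cases and samples about twice as many non-cases.
Defaults for clinical covariates (age 64 ± 9, 20% female, BMI 28 ± 4.5,
20% smokers, 35% diabetes, 70% hypertension) are typical of secondary
prevention trial populations.

What the generators deliberately omit: assay cross-reactivity (the PEA
design premise is pairwise probe specificity), competing risks,
covariate missingness, plate-position effects, and lot-to-lot calibrator
drift.  Passing tests therefore demonstrate the correctness of the
computational pipeline under its stated model, not robustness of the assay
chemistry or transportability to real plasma data.

# Problem sizes and determinism

Tests and the acceptance script use scaled-down but structurally faithful
designs chosen to characterize each property well: 21-assay plates with
30-point, two-run calibration series; 100-seed calibration-recovery
studies; 200-seed coverage and imputation studies at cohort sizes of
1200–2500; bootstrap depths of 30–100 within studies whose quantity of
interest is a direction or rate rather than a variance.  Every stochastic
routine takes an explicit integer seed, and all reported numbers are
recomputed at run time from those seeds.

# Known limitations

* Breslow tie handling only (adequate at the simulated tie rates; Efron
  would be preferable for coarsely discretized times).
* LLOQ/ULOQ resolution is bounded by the two-fold standard spacing.
* Value reassignment is a single multiplicative scale; method differences
  with concentration-dependent bias would need a curve-shape recalibration
  that the reassignment model intentionally does not attempt.
* The pairwise C bootstrap treats fitted scores as fixed, so it quantifies
  ranking uncertainty given the models, not model-selection uncertainty.
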