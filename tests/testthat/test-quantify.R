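test_that("4PL fit recovers generating parameters from noiseless designs", {
  # increasing orientation (b < 0), the panel's own geometry
  tr <- small_truth()
  for (j in 1:3) {
    sc <- simulate_standard_curve(tr[j, ], npx_noise_sd = 0, seed = j)
    cv <- fit_4pl(sc$conc, sc$npx)
    expect_equal(cv$a, tr$a[j], tolerance = 1e-6)
    expect_equal(cv$c, tr$c[j], tolerance = 1e-6)
    expect_equal(cv$b, tr$b[j], tolerance = 1e-6)
  }
  # decreasing orientation (a = 10, d = 0, c = 50, b = 1)
  x <- 50 * 2^seq(5, -24)
  npx <- 0 + 10 / (1 + (x / 50))
  cv2 <- fit_4pl(c(x, 0, 0), c(npx, 10, 10))
  expect_equal(cv2$c, 50, tolerance = 1e-6)
  expect_equal(cv2$b, 1, tolerance = 1e-6)
})

test_that("fitted curve passes through (c, (a+d)/2) and fit preconditions hold", {
  tr <- small_truth()
  sc <- simulate_standard_curve(tr[1, ], npx_noise_sd = 0, seed = 1)
  cv <- fit_4pl(sc$conc, sc$npx)
  expect_equal(fourpl(cv$c, cv$a, cv$d, cv$c, cv$b), (cv$a + cv$d) / 2)
  expect_error(fit_4pl(c(1, 2, 4, 8), c(1, 2, 3, 4)), "blank")
})

test_that("inflection recovery under replicate noise succeeds in most seeds", {
  tr <- small_truth()[1, ]
  errs <- vapply(1:40, function(s) {
    sc <- simulate_standard_curve(tr, npx_noise_sd = 0.1, seed = s)
    cv <- fit_4pl(sc$conc, sc$npx)
    abs(cv$c - tr$c) / tr$c
  }, numeric(1))
  expect_gte(mean(errs < 0.10), 0.9)
})

test_that("curve inversion is the algebraic inverse", {
  tr <- small_truth()
  sc <- simulate_standard_curve(tr[2, ], npx_noise_sd = 0, seed = 2)
  cv <- fit_4pl(sc$conc, sc$npx)
  # round trip at an arbitrary concentration
  x <- 7.3
  expect_equal(as.numeric(invert_4pl(cv, fourpl(x, cv$a, cv$d, cv$c, cv$b))),
               x, tolerance = 1e-9)
  # across the open response interval
  xs <- 10^seq(-3, 3, length.out = 50) * cv$c
  back <- as.numeric(invert_4pl(cv, fourpl(xs, cv$a, cv$d, cv$c, cv$b)))
  expect_equal(back, xs, tolerance = 1e-9)
  # midpoint maps to the inflection
  expect_equal(as.numeric(invert_4pl(cv, (cv$a + cv$d) / 2)), cv$c,
               tolerance = 1e-12)
  # approaching the high-concentration asymptote diverges monotonically
  npx_seq <- cv$a - 10^seq(-1, -6, length.out = 6) * (cv$a - cv$d)
  xinv <- as.numeric(invert_4pl(cv, npx_seq))
  expect_true(all(diff(xinv) > 0))
  # outside (d, a): censored, with the side recorded
  out <- invert_4pl(cv, c(cv$a + 1, cv$d - 1))
  expect_true(all(is.na(as.numeric(out))))
  expect_identical(attr(out, "side"), c("high", "low"))
})

test_that("LOD is blank mean plus three standard deviations", {
  tr <- small_truth()
  sc <- simulate_standard_curve(tr[1, ], npx_noise_sd = 0, seed = 1)
  cv <- fit_4pl(sc$conc, sc$npx)
  cv1 <- determine_lod(cv, c(0.0, 0.1, -0.1))
  expect_equal(cv1$lod_npx, 0.3)
  # zero spread: LOD equals the blank mean
  cv2 <- determine_lod(cv, c(0.2, 0.2, 0.2))
  expect_equal(cv2$lod_npx, 0.2)
  # doubling the spread doubles the margin over the mean
  cv3 <- determine_lod(cv, c(0.0, 0.2, -0.2))
  expect_equal(cv3$lod_npx - 0, 2 * (cv1$lod_npx - 0))
  expect_error(determine_lod(cv, 0.1), "2 blank")
})

test_that("LLOQ/ULOQ follow the 30% accuracy and precision rule", {
  tr <- small_truth()
  sc <- simulate_standard_curve(tr[1, ], npx_noise_sd = 0, seed = 1)
  cv <- fit_4pl(sc$conc, sc$npx)
  cv <- determine_loq(cv, sc$conc, sc$npx, predilution = 10)
  pos <- sort(unique(sc$conc[sc$conc > 0]))
  expect_true(cv$quantitative)
  expect_equal(cv$lloq_conc, min(pos) * 10)
  expect_equal(cv$uloq_conc, max(pos) * 10)

  # replicates {8, 12} at nominal 10: accuracy 0, precision 28.3% -> pass
  cv_id <- cv; cv_id$a <- 10; cv_id$d <- 0; cv_id$c <- 1; cv_id$b <- -1
  back_npx <- fourpl(c(8, 12), 10, 0, 1, -1)
  many <- c(0.1, 1, 40)
  cv2 <- determine_loq(cv_id,
                       conc = c(10, 10, rep(many, each = 2)),
                       npx = c(back_npx, fourpl(rep(many, each = 2),
                                                10, 0, 1, -1)))
  tab <- attr(cv2, "loq_table")
  row10 <- tab[tab$nominal == 10, ]
  expect_equal(row10$accuracy, 0, tolerance = 1e-12)
  expect_equal(row10$precision, sd(c(8, 12)) / 10, tolerance = 1e-12)
  expect_true(row10$pass)
  expect_equal(row10$precision, 0.2828, tolerance = 1e-3)
})

test_that("LOQ determination is idempotent and order-invariant", {
  tr <- small_truth()
  sc <- simulate_standard_curve(tr[2, ], npx_noise_sd = 0.1, seed = 5)
  cv <- fit_4pl(sc$conc, sc$npx)
  a1 <- determine_loq(cv, sc$conc, sc$npx, predilution = 10)
  a2 <- determine_loq(a1, sc$conc, sc$npx, predilution = 10)
  expect_equal(a1$lloq_conc, a2$lloq_conc)
  expect_equal(a1$uloq_conc, a2$uloq_conc)
  perm <- sample(length(sc$conc))
  a3 <- determine_loq(cv, sc$conc[perm], sc$npx[perm], predilution = 10)
  expect_equal(a1$lloq_conc, a3$lloq_conc)
  expect_equal(a1$uloq_conc, a3$uloq_conc)
})

test_that("a desensitized assay is flagged non-quantitative", {
  # inflection far above every standard: response is flat, back-calculation
  # noise overwhelms the 30% rule
  cv <- structure(list(assay_id = "dead", a = 10, d = 0, c = 1e9, b = -1,
                       rss = NA_real_, n_points = 10L, lod_npx = NA_real_,
                       lod_conc = NA_real_, lloq_conc = NA_real_,
                       uloq_conc = NA_real_, quantitative = NA, scale = 1),
                  class = "standard_curve")
  set.seed(1)
  conc <- rep(2^(0:9), each = 2)
  npx <- fourpl(conc, 10, 0, 1e9, -1) + rnorm(length(conc), 0, 0.05)
  cv <- determine_loq(cv, conc, npx)
  expect_false(cv$quantitative)
  expect_true(is.na(cv$lloq_conc))
})

test_that("value reassignment estimates the multiplicative scale exactly", {
  tr <- small_truth()
  sc <- simulate_standard_curve(tr[1, ], npx_noise_sd = 0, seed = 1)
  cv <- fit_4pl(sc$conc, sc$npx)
  cv <- determine_lod(cv, rep(0, 3) + c(-0.05, 0, 0.05))
  cv <- determine_loq(cv, sc$conc, sc$npx, predilution = 10)
  pea <- exp(runif(20, log(cv$lloq_conc * 2), log(cv$uloq_conc / 2)))
  # reference exactly double
  r2 <- reassign_values(cv, pea, 2 * pea)
  expect_equal(attr(r2, "last_scale"), 2)
  expect_equal(r2$c, cv$c * 2)
  expect_equal(r2$lloq_conc, cv$lloq_conc * 2)
  # identity leaves the curve unchanged
  r1 <- reassign_values(cv, pea, pea)
  expect_equal(attr(r1, "last_scale"), 1)
  expect_equal(r1$c, cv$c)
  # after reassignment the mean log2 ratio is zero on the pairs
  set.seed(2)
  ref <- pea * 2^rnorm(20, 0.4, 0.2)
  r3 <- reassign_values(cv, pea, ref)
  pea_re <- pea * attr(r3, "last_scale")
  expect_equal(mean(log2(pea_re / ref)), 0, tolerance = 1e-12)
  # a second application is a no-op
  r4 <- reassign_values(r3, pea_re, ref)
  expect_equal(attr(r4, "last_scale"), 1, tolerance = 1e-12)
  # too few in-range pairs errors
  expect_error(suppressMessages(reassign_values(cv, rep(cv$lloq_conc / 2, 20),
                                                rep(1, 20))),
               "at least")
})

test_that("zero-noise pipeline recovers true concentrations end to end", {
  tr <- small_truth(ct_noise_sd = 0)
  panel <- panel_from_truth(tr, reassigned = character())
  std <- standard_series(tr, n_conc = 30)
  pt_std <- simulate_plates(tr, n_plates = 2, n_samples = 30, seed = 11,
                            sample_conc = rbind(std, std))
  curves <- fit_standard_curves(npx_from_plate(pt_std), std, panel)
  pt <- simulate_plates(tr, n_plates = 1, n_samples = 20, seed = 12)
  q <- quantify_samples(npx_from_plate(pt), curves, panel)
  truth <- attr(pt, "true_conc")
  m <- merge(q, truth[truth$role == "sample", ],
             by = c("plate_id", "well_id", "assay_id"))
  inr <- m$flag == "in_range"
  expect_gt(sum(inr), 0)
  expect_lt(max(abs(m$conc[inr] - m$true_conc[inr]) / m$true_conc[inr]),
            1e-6)
})

test_that("quantification flags respect curve bounds", {
  tr <- small_truth()
  sc <- simulate_standard_curve(tr[1, ], npx_noise_sd = 0, seed = 1)
  cv <- fit_4pl(sc$conc, sc$npx, "A1")
  cv$lod_conc <- 1; cv$lloq_conc <- 10; cv$uloq_conc <- 1e4
  cvs <- standard_curve_set(list(cv))
  panel <- pea_panel("p", data.frame(assay_id = "A1"))
  mk <- function(npx) data.frame(plate_id = "P1", well_id = "W01",
                                 sample_id = "S", role = "sample",
                                 assay_id = "A1", dct = 0, ddct = 0,
                                 npx = npx)
  flag_of <- function(npx)
    quantify_samples(mk(npx), cvs, panel)$flag
  expect_equal(flag_of(cv$a + 0.5), "above_uloq")   # beyond upper asymptote
  expect_equal(flag_of(cv$d - 0.5), "below_lod")    # beyond lower asymptote
  expect_equal(flag_of(fourpl(50 / 10, cv$a, cv$d, cv$c, cv$b)), "in_range")
  expect_equal(flag_of(fourpl(5 / 10, cv$a, cv$d, cv$c, cv$b)), "below_lloq")
  expect_equal(flag_of(fourpl(0.05 / 10, cv$a, cv$d, cv$c, cv$b)),
               "below_lod")
})

test_that("censored lognormal imputation honours bounds and is deterministic", {
  set.seed(7)
  v <- rlnorm(200, 2, 0.5)
  lloq <- qlnorm(0.2, 2, 0.5)
  flag <- ifelse(v < lloq, "below_lloq", "in_range")
  vv <- ifelse(v < lloq, NA, v)
  imp1 <- impute_censored(vv, flag, lloq, uloq = 1e6, seed = 4)
  imp2 <- impute_censored(vv, flag, lloq, uloq = 1e6, seed = 4)
  expect_identical(as.numeric(imp1), as.numeric(imp2))
  expect_true(all(imp1[flag == "below_lloq"] < min(vv, na.rm = TRUE)))
  # no censoring: no-op
  imp3 <- impute_censored(v, rep("in_range", 200), lloq, 1e6, seed = 1)
  expect_identical(as.numeric(imp3), v)
  # right censoring respects the lower bound
  uloq <- qlnorm(0.9, 2, 0.5)
  flag2 <- ifelse(v > uloq, "above_uloq", flag)
  vv2 <- ifelse(v > uloq, NA, vv)
  imp4 <- impute_censored(vv2, flag2, lloq, uloq, seed = 2)
  expect_true(all(imp4[flag2 == "above_uloq"] > uloq))
})

test_that("censored MLE recovers lognormal parameters across seeds", {
  res <- t(vapply(1:30, function(s) {
    set.seed(s)
    v <- rlnorm(200, 2, 0.5)
    lloq <- qlnorm(0.2, 2, 0.5)
    flag <- ifelse(v < lloq, "below_lloq", "in_range")
    vv <- ifelse(v < lloq, NA, v)
    imp <- impute_censored(vv, flag, lloq, 1e6, seed = s)
    c(attr(imp, "meanlog"), attr(imp, "sdlog"))
  }, numeric(2)))
  expect_equal(mean(res[, 1]), 2, tolerance = 0.1)
  expect_equal(mean(res[, 2]), 0.5, tolerance = 0.1)
})
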