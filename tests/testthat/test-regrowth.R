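test_that("exponential fit recovers rate and initial OD from clean curves", {
  f <- fit_exponential(make_exp_series(r = 0.5, od0 = 0.02))
  expect_equal(f$r, 0.5, tolerance = 1e-9)
  expect_equal(f$od0, 0.02, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_true(f$accepted)

  # a 1 h lag is folded into the intercept: od0 = 0.02 * exp(-0.5)
  f_lag <- fit_exponential(make_exp_series(r = 0.5, od0 = 0.02, lag = 1))
  expect_equal(f_lag$r, 0.5, tolerance = 1e-9)
  expect_equal(f_lag$od0, 0.02 * exp(-0.5), tolerance = 1e-6)

  expect_error(fit_exponential(make_exp_series(times = c(0, 1, 2))),
               "insufficient")
  s <- od_series("w", "c", 1, 0:5, c(0, 0.01, 0.02, 0.04, 0.08, 0.16))
  expect_error(fit_exponential(s, window = c(0, 5)), "OD <= 0")
})

test_that("noisy exponential curves are recovered across many seeds", {
  errs <- t(vapply(1:200, function(seed) {
    s <- make_exp_series(r = 0.7, od0 = 0.005, noise_sd = 0.02,
                         times = seq(0, 10, 0.25), seed = seed)
    f <- fit_exponential(s)
    c(r = abs(f$r / 0.7 - 1), od0 = abs(f$od0 / 0.005 - 1))
  }, numeric(2)))
  expect_lt(median(errs[, "r"]), 0.05)
  expect_lt(median(errs[, "od0"]), 0.05)
})

test_that("logistic difference fit recovers r and k; exponential limit holds", {
  ts <- seq(0, 12, 0.1)
  s <- od_series("w", "c", 1, ts, logistic_od(0.01, 0.8, 1.2, ts),
                 medium_class = "rich")
  f <- fit_logistic_difference(s)
  expect_rel_equal(f$r, 0.8, 0.02)
  expect_rel_equal(f$k, 1.2, 0.02)
  expect_rel_equal(f$od0, 0.01, 0.02)

  # deep exponential regime: logistic and exponential rates agree within 5%
  ts2 <- seq(0, 4, 0.1)
  od2 <- logistic_od(0.001, 0.8, 5, ts2)   # max OD << k
  s2 <- od_series("w", "c", 1, ts2, od2)
  f_log <- suppressWarnings(fit_logistic_difference(s2))
  f_exp <- fit_exponential(s2, window = c(0, 4))
  expect_rel_equal(f_log$r, f_exp$r, 0.05)

  expect_error(
    fit_logistic_difference(od_series("w", "c", 1, 0:6, rep(0.5, 7))),
    "constant")
})

test_that("logistic back-extrapolation satisfies its closed-form identities", {
  # t0 = 0 identity
  expect_equal(back_extrapolate_od0(1, 1.5, 0.4, 0), 0.4)
  # hand-computed point: r = 1, k = 1, OD(t0) = 0.5, t0 = ln 3 -> 0.25
  expect_equal(back_extrapolate_od0(1, 1, 0.5, log(3)), 0.25,
               tolerance = 1e-12)
  # large-k exponential limit
  expect_equal(back_extrapolate_od0(1, 1e6, 0.5, 2), 0.5 * exp(-2),
               tolerance = 1e-4)
  # composition with forward propagation is the identity
  withr::with_seed(7, {
    for (i in 1:25) {
      od0 <- runif(1, 1e-4, 0.1); r <- runif(1, 0.2, 1.5)
      k <- runif(1, 0.5, 2); t0 <- runif(1, 0, 8)
      od_t0 <- logistic_od(od0, r, k, t0)
      expect_equal(back_extrapolate_od0(r, k, od_t0, t0) / od0, 1,
                   tolerance = 1e-10)
    }
  })
  expect_error(back_extrapolate_od0(1, 1, 1.5, 0), "carrying capacity")
  expect_error(back_extrapolate_od0(-1, 1, 0.5, 0), "r must be")
})

test_that("regrowth viability is the paired od0 ratio with its t test", {
  fits <- lapply(1:4, function(i) fit_exponential(make_exp_series()))
  # self-viability is exactly 1, indifferent test
  v <- viability_from_regrowth(fits, fits)
  expect_equal(v$per_replicate, rep(1, 4))
  expect_equal(v$viability, 1)
  expect_equal(v$test$p_value, 0.5)

  # pure lag of 1 h at r = ln 2 halves the estimated viability
  r <- log(2)
  treated <- lapply(1:4, function(i)
    fit_exponential(make_exp_series(r = r, lag = 1, times = seq(0, 6, 0.25))))
  controls <- lapply(1:4, function(i)
    fit_exponential(make_exp_series(r = r, times = seq(0, 6, 0.25))))
  v2 <- viability_from_regrowth(treated, controls)
  expect_equal(v2$viability, 0.5, tolerance = 1e-6)

  # lag monotonicity: viability falls as exp(-r * lag)
  vias <- vapply(c(0.5, 1, 2), function(lag) {
    tr <- list(fit_exponential(make_exp_series(r = r, lag = lag,
                                               times = seq(0, 7, 0.25))))
    viability_from_regrowth(tr, controls[1])$viability
  }, numeric(1))
  expect_equal(vias, exp(-r * c(0.5, 1, 2)), tolerance = 1e-5)
  expect_true(all(diff(vias) < 0))

  expect_error(viability_from_regrowth(fits, fits[1:2]), "pairing")
})

test_that("simulated treatment at 88% viability is recovered without bias", {
  ests <- vapply(1:20, function(seed) {
    g <- gen_growth_curves(model = "exponential", r = 0.7,
                           od0_control = 0.005, viability_true = 0.88,
                           noise_sd_log = 0.02, n_replicates = 4,
                           horizon_h = 10, seed = seed)
    viability_from_regrowth(lapply(g$treated, fit_exponential),
                            lapply(g$control, fit_exponential))$viability
  }, numeric(1))
  # experiment-level estimates scatter around the truth
  expect_lt(abs(mean(ests) - 0.88), 3 * sd(ests) / sqrt(length(ests)))
  expect_lt(sd(ests), 0.02)
})

test_that("growth-rate effect test flags rate reductions only", {
  controls <- lapply(1:4, function(i)
    fit_exponential(make_exp_series(r = 0.7, noise_sd = 0.005, seed = i)))
  same <- lapply(5:8, function(i)
    fit_exponential(make_exp_series(r = 0.7, noise_sd = 0.005, seed = i)))
  halved <- lapply(9:12, function(i)
    fit_exponential(make_exp_series(r = 0.35, noise_sd = 0.005, seed = i,
                                    times = seq(0, 10, 0.25))))
  expect_gt(growth_rate_effect(same, controls)$p_value, 0.05)
  expect_lt(growth_rate_effect(halved, controls)$p_value, 0.05)
  expect_error(growth_rate_effect(controls[1], controls[1]), "degenerate")
})

test_that("QC-rejected fits are refused unless overridden", {
  wiggly <- make_exp_series(r = 0.5, od0 = 0.02, noise_sd = 0.3, seed = 1)
  f_bad <- fit_exponential(wiggly)
  expect_false(f_bad$accepted)
  good <- fit_exponential(make_exp_series())
  expect_error(viability_from_regrowth(list(f_bad), list(good)), "QC")
  expect_s3_class(
    viability_from_regrowth(list(f_bad), list(good), allow_rejected = TRUE),
    "viability_estimate")
})

test_that("MIC endpoint scan enforces monotonicity and censors correctly", {
  res <- mic_from_endpoint(c(0, 12.5, 25, 50, 100),
                           c(1.0, 0.9, 0.8, 0.05, 0.04))
  expect_equal(res$mic, 50)
  expect_equal(res$censored, "none")
  expect_equal(res$threshold, 0.1)

  # growth everywhere: right-censored above the top tested concentration
  grow <- mic_from_endpoint(c(0, 400, 800, 1600), c(1.0, 0.9, 0.9, 0.8))
  expect_true(is.na(grow$mic))
  expect_equal(grow$censored, "> max")

  # suppression already at the lowest concentration: left-censored
  low <- mic_from_endpoint(c(0, 3.125, 6.25), c(1.0, 0.02, 0.01))
  expect_equal(low$mic, 3.125)
  expect_equal(low$censored, "<= min")

  # non-monotone well raises the MIC past the growing concentration
  expect_warning(
    nm <- mic_from_endpoint(c(0, 25, 50, 100, 200, 400),
                            c(1.0, 0.9, 0.05, 0.8, 0.04, 0.03)),
    "non-monotone")
  expect_equal(nm$mic, 200)
  expect_true(nm$non_monotone)

  expect_error(mic_from_endpoint(c(0, 50), c(0.02, 0.01)), "no-growth")

  ref <- mic_from_endpoint(c(0, 12.5, 25, 50), c(1.0, 0.04, 0.03, 0.02),
                           reference_mic = 12.5)
  expect_equal(ref$fold_change_vs_reference, 1)
})
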