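test_that("generators are deterministic under a fixed seed", {
  g1 <- gen_growth_curves(seed = 8)
  g2 <- gen_growth_curves(seed = 8)
  expect_identical(g1$control[[1]]$ods, g2$control[[1]]$ods)
  expect_identical(g1$treated[[3]]$ods, g2$treated[[3]]$ods)

  expect_identical(
    suppressWarnings(gen_flow_events(1000, seed = 8))$red_intensity,
    suppressWarnings(gen_flow_events(1000, seed = 8))$red_intensity)
  expect_identical(gen_bead_set(noise_frac = 0.02, seed = 8)$bead_points,
                   gen_bead_set(noise_frac = 0.02, seed = 8)$bead_points)
  expect_identical(gen_point_aggregate(50, "both_strands", seed = 8)$points,
                   gen_point_aggregate(50, "both_strands", seed = 8)$points)
  expect_identical(gen_lineage(seed = 8)$traces[[2]]$mean_fluorescences,
                   gen_lineage(seed = 8)$traces[[2]]$mean_fluorescences)

  # generators do not disturb the global RNG stream
  withr::with_seed(99, {
    a <- runif(1)
  })
  withr::with_seed(99, {
    invisible(gen_growth_curves(seed = 3))
    b <- runif(1)
  })
  expect_identical(a, b)
})

test_that("every generator embeds its ground truth", {
  expect_equal(gen_growth_curves(viability_true = 0.7,
                                 seed = 1)$truth$viability_true, 0.7)
  small_ev <- suppressWarnings(gen_flow_events(500, live_frac = 0.8,
                                               seed = 1))
  expect_equal(small_ev$truth$live_frac, 0.8)
  expect_equal(gen_bead_set(slope_true = 0.25, seed = 1)$truth$slope_true,
               0.25)
  expect_equal(gen_aggregation_od(0.005, n_cells_per_color = 200,
                                  duration_h = 0.1, seed = 1)$truth$p, 0.005)
  expect_equal(gen_point_aggregate(50, "random", seed = 1)$truth$regime,
               "random")
  expect_equal(gen_lineage(f_true = 0.6, seed = 1)$truth$f_true, 0.6)
})

test_that("zero-noise growth generator is closed-form and fits exactly", {
  g <- gen_growth_curves(model = "exponential", r = 0.7, od0_control = 0.005,
                         viability_true = 1, lag_h = 0, noise_sd_log = 0,
                         n_replicates = 2, seed = 1)
  expect_equal(g$treated[[1]]$ods, g$control[[1]]$ods)

  g2 <- gen_growth_curves(model = "exponential", viability_true = 0.5,
                          noise_sd_log = 0, n_replicates = 2, seed = 1)
  v <- viability_from_regrowth(lapply(g2$treated, fit_exponential),
                               lapply(g2$control, fit_exponential))
  expect_equal(v$viability, 0.5, tolerance = 1e-9)

  # logistic branch feeds the logistic fitter
  g3 <- gen_growth_curves(model = "logistic", r = 0.8, k = 1.2,
                          od0_control = 0.01, noise_sd_log = 0,
                          n_replicates = 1, dt_h = 0.1, seed = 1)
  f <- fit_logistic_difference(g3$control[[1]])
  expect_rel_equal(f$r, 0.8, 0.02)
  expect_rel_equal(f$k, 1.2, 0.02)
})

test_that("flow-event generator round-trips through stain viability", {
  ev <- gen_flow_events(10000, live_frac = 0.9, seed = 13)
  ctrl <- gen_flow_events(10000, live_frac = 1, seed = 14)
  sv <- stain_viability(ev, ctrl, threshold = 500)
  expect_lt(abs(sv$viable_fraction_sample - ev$truth$live_frac_realized),
            0.01)
  # live_frac = 1 leaves the dead mode empty
  expect_equal(mean(ctrl$red_intensity > 1000), 0, tolerance = 0.001)
})

test_that("bead generator with zero noise reproduces the exact line", {
  b <- gen_bead_set(slope_true = 0.2, blank = 30, noise_frac = 0, seed = 1)
  expect_equal(b$bead_points$mfi,
               30 + 0.2 * b$bead_points$molecules_per_bead)
  cal <- fit_mesf_calibration(b$bead_points, b$blank_mfi)
  expect_equal(cal$slope, 0.2, tolerance = 1e-12)
  expect_error(gen_bead_set(molecule_counts = c(1e4, 1e4)), "distinct")
})

test_that("recover-all: each generator feeds its fitter to tolerance", {
  # growth: 88% viability, 4 replicates, 2% log-noise, many experiments
  ests <- vapply(1:10, function(seed) {
    g <- gen_growth_curves(viability_true = 0.88, noise_sd_log = 0.02,
                           n_replicates = 4, horizon_h = 10, seed = seed)
    viability_from_regrowth(lapply(g$treated, fit_exponential),
                            lapply(g$control, fit_exponential))$viability
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.88), 3 * sd(ests) / sqrt(length(ests)))

  # beads at 1% noise: slope within 3%
  b <- gen_bead_set(noise_frac = 0.01, seed = 4)
  expect_rel_equal(fit_mesf_calibration(b$bead_points, b$blank_mfi)$slope,
                   b$truth$slope_true, 0.03)

  # aggregation: fitted p within 15% median over seeds
  m <- aggregation_model()
  errs <- vapply(1:15, function(s) {
    sim <- gen_aggregation_od(0.01, m, duration_h = 1,
                              n_cells_per_color = 2000, seed = s)
    f <- fit_adhesion_rate(sim$od_trace, model = m,
                           max_aggregated_frac = 0.15)
    abs(f$p / 0.01 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.15)

  # lineage: noisy median f within 0.05 of truth
  gl <- gen_lineage(f_true = 0.5, partition_noise = 0.1, n_lineages = 6,
                    seed = 5)
  fs <- vapply(gl$traces, function(tr) fit_retention(tr)$f, numeric(1))
  expect_lt(abs(median(fs) - 0.5), 0.05)
})
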