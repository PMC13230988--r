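#' Physical model constants for aggregation kinetics
#'
#' Bundles the constants needed to convert a coagulation rate measured in
#' OD600 units into a per-encounter adhesion probability. The diffusive
#' encounter rate between two equal-sized cells is `4*pi*D_eff*R_c` with
#' `D_eff = 2D` and encounter radius `R_c = 2R`; with the Stokes-Einstein
#' relation `D = kB*T/(6*pi*R*eta)` the cell radius cancels and the
#' volumetric adhesion rate is `k_vol = 8*kB*T/(3*eta) * p`.
#'
#' @param c0 Initial concentration of each of the two populations, OD600
#'   units (initial total OD = 2*c0).
#' @param temperature_K Absolute temperature (default 298.15 K, 25 C
#'   incubation).
#' @param viscosity_Pas Dynamic viscosity (default 0.89e-3 Pa s, water at
#'   25 C; 1.0e-3 is accepted for round-number checks).
#' @param cells_per_ml_per_od Number density per ml per OD600 unit
#'   (default 1e9).
#' @return A list of class `aggregation_model`.
#' @export
aggregation_model <- function(c0 = 0.5, temperature_K = 298.15,
                              viscosity_Pas = 0.89e-3,
                              cells_per_ml_per_od = 1e9) {
  stopifnot(c0 > 0, temperature_K > 0, viscosity_Pas > 0,
            cells_per_ml_per_od > 0)
  structure(list(c0 = c0, temperature_K = temperature_K,
                 viscosity_Pas = viscosity_Pas,
                 cells_per_ml_per_od = cells_per_ml_per_od),
            class = "aggregation_model")
}

BOLTZMANN_J_PER_K <- 1.380649e-23

#' Analytic OD decay of first-order two-population coagulation
#'
#' Two populations at equal initial concentration `c0` react pairwise at
#' rate `k_od`; counting single cells and two-cell aggregates as equal
#' scatterers, `OD(t) = c0 + c0 / (c0 * k_od * t + 1)`. The curve starts at
#' `2*c0`, decreases monotonically and approaches `c0` as all cells pair up.
#'
#' @param c0 Initial concentration of each population, OD600 units.
#' @param k_od Reaction rate, (OD600 * hour)^-1.
#' @param t Time, hours (vectorized).
#' @return OD600 value(s).
#' @export
od_curve <- function(c0, k_od, t) {
  stopifnot(c0 > 0, k_od >= 0, all(t >= 0))
  c0 + c0 / (c0 * k_od * t + 1)
}

#' Convert an OD-units coagulation rate to an adhesion probability
#'
#' The OD-units rate is first converted to a volumetric rate using the
#' number density `n = cells_per_ml_per_od * 1e6` cells per m^3 per OD:
#' `k_vol = k_od / (n * 3600)` in m^3/s. The per-encounter adhesion
#' probability is then `p = 3 * eta * k_vol / (8 * kB * T)`; the cell
#' radius cancels exactly. Values above 1 are physically suspect and
#' flagged with a warning but returned.
#'
#' @param k_od Reaction rate, (OD600 * hour)^-1.
#' @param model An [aggregation_model()].
#' @return Adhesion probability per encounter (dimensionless).
#' @export
rate_to_probability <- function(k_od, model = aggregation_model()) {
  stopifnot(inherits(model, "aggregation_model"), all(k_od >= 0))
  n_per_m3 <- model$cells_per_ml_per_od * 1e6
  k_vol <- k_od / (n_per_m3 * 3600)
  p <- 3 * model$viscosity_Pas * k_vol /
    (8 * BOLTZMANN_J_PER_K * model$temperature_K)
  if (any(p > 1))
    warning("adhesion probability exceeds 1; fitted rate is faster than ",
            "the diffusion limit", call. = FALSE)
  p
}

#' Inverse of [rate_to_probability()]
#'
#' @param p Adhesion probability per encounter.
#' @param model An [aggregation_model()].
#' @return Reaction rate in (OD600 * hour)^-1.
#' @export
probability_to_rate <- function(p, model = aggregation_model()) {
  stopifnot(inherits(model, "aggregation_model"), all(p >= 0))
  n_per_m3 <- model$cells_per_ml_per_od * 1e6
  k_vol <- p * 8 * BOLTZMANN_J_PER_K * model$temperature_K /
    (3 * model$viscosity_Pas)
  k_vol * n_per_m3 * 3600
}

#' Fit the first-order coagulation rate to a sedimentation trace
#'
#' Nonlinear least squares of [od_curve()] against the early part of a
#' sedimentation OD600 trace (default: the first 60 minutes, where the
#' single-cell pairing reaction dominates and the first-order model is
#' valid). `c0` is fixed, by default at half the first OD reading.
#' Confidence intervals are Wald intervals from the least-squares parameter
#' covariance (t quantile at the window's degrees of freedom). A
#' sensitivity report re-fits over 30/45/60-minute windows.
#'
#' @param series An [od_series()] of sedimentation readings (time 0 at
#'   mixing).
#' @param c0 Initial per-population concentration in OD units; `NULL`
#'   (default) fixes `c0 = OD(first point) / 2`.
#' @param window_h Fit window length in hours from the first time point.
#' @param max_aggregated_frac Optional early-regime guard: the window is
#'   additionally truncated at the first reading where the aggregated
#'   fraction `(2*c0 - OD) / c0` exceeds this value. The first-order model
#'   ignores reactions involving multicell aggregates, so it is only valid
#'   while most cells are single; 0.1-0.2 keeps the fit inside that regime
#'   for fast-aggregating samples. `NULL` (default) disables the guard.
#' @param model An [aggregation_model()] used to convert the fitted rate to
#'   an adhesion probability (its `c0` field is ignored in favour of the
#'   `c0` argument).
#' @param conf_level Confidence level for the intervals.
#' @return A list of class `aggregation_fit`: `k_od` with `k_ci`, `p` with
#'   `p_ci`, `c0`, `window`, `residual_sd`, `no_aggregation` flag, and
#'   `sensitivity` (data frame of k over the 30/45/60-min windows).
#' @export
fit_adhesion_rate <- function(series, c0 = NULL, window_h = 1,
                              model = aggregation_model(),
                              conf_level = 0.95,
                              max_aggregated_frac = NULL) {
  stopifnot(inherits(series, "od_series"))
  t <- series$times - series$times[1]
  od <- series$ods
  if (is.null(c0)) c0 <- od[1] / 2
  if (abs(od[1] - 2 * c0) > 0.1 * 2 * c0)
    warning("first OD reading deviates more than 10% from 2*c0",
            call. = FALSE)
  in_win <- t <= window_h
  if (!is.null(max_aggregated_frac)) {
    over <- which((2 * c0 - od) > max_aggregated_frac * c0)
    if (length(over) > 0) in_win <- in_win & seq_along(t) < min(over)
  }
  if (sum(in_win) < 5L)
    stop("insufficient data: need >= 5 points within the fit window",
         call. = FALSE)
  tw <- t[in_win]
  yw <- od[in_win]
  # t quantile rather than normal: small-sample widening improves the
  # nominal coverage of the Wald interval
  z <- stats::qt(1 - (1 - conf_level) / 2, df = sum(in_win) - 1)

  fit_one <- function(tt, yy) {
    slope <- unname(stats::coef(stats::lm(yy ~ tt))[2])
    if (slope >= 0 || diff(range(yy)) < 1e-10) {
      return(list(k = 0, se = NA_real_, rsd = stats::sd(yy), flat = TRUE))
    }
    # linearization 1/(OD/c0 - 1) = c0*k*t + 1 seeds the start value
    lin <- pmax(yy / c0 - 1, 1e-8)
    k_start <- max(unname(stats::coef(stats::lm(I(1 / lin) ~ tt))[2]) / c0,
                   1e-6)
    nl <- minpack.lm::nlsLM(
      yy ~ c0 + c0 / (c0 * k * tt + 1),
      start = list(k = k_start), lower = c(k = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    list(k = unname(stats::coef(nl)["k"]),
         se = summary(nl)$coefficients["k", "Std. Error"],
         rsd = summary(nl)$sigma, flat = FALSE)
  }

  main <- fit_one(tw, yw)
  sens <- do.call(rbind, lapply(c(0.5, 0.75, 1), function(frac) {
    wh <- frac * window_h
    sel <- t <= wh
    if (sum(sel) < 5L) return(NULL)
    f <- fit_one(t[sel], od[sel])
    data.frame(window_h = wh, k_od = f$k)
  }))

  k_ci <- if (main$flat) c(0, 0) else
    pmax(main$k + c(-1, 1) * z * main$se, 0)
  p <- rate_to_probability(main$k, model)
  p_ci <- rate_to_probability(k_ci, model)
  structure(list(k_od = main$k, k_ci = k_ci, p = p, p_ci = p_ci, c0 = c0,
                 window = c(series$times[1], series$times[1] + window_h),
                 residual_sd = main$rsd, no_aggregation = main$flat,
                 sensitivity = sens),
            class = "aggregation_fit")
}

#' @export
print.aggregation_fit <- function(x, ...) {
  if (x$no_aggregation) {
    cat("<aggregation_fit> no aggregation detected (OD non-decreasing); k = 0\n")
  } else {
    cat(sprintf(
      "<aggregation_fit> k = %.4g (%.4g-%.4g) /(OD h); p = %.4g (%.4g-%.4g)\n",
      x$k_od, x$k_ci[1], x$k_ci[2], x$p, x$p_ci[1], x$p_ci[2]))
  }
  invisible(x)
}

#' Stochastic coagulation oracle (Gillespie, constant kernel)
#'
#' Exact stochastic simulation of the two-population aggregation assay:
#' every pair of clusters in which one member contains a red cell and the
#' other a green cell reacts at a constant (size-independent) per-pair rate
#' chosen so the mean-field limit reproduces [od_curve()] at the `k_od`
#' implied by `p`. Same-color reactions are off by default (the complement
#' model contains none) but a background same-color rate is available for
#' emulating the non-complementary control. The OD proxy is the cluster
#' count scaled so OD(0) = 2*c0; total cell count is conserved.
#'
#' @param n_cells_per_color Cells per population (>= 100).
#' @param p Adhesion probability per encounter in \[0, 1\].
#' @param model An [aggregation_model()] (supplies `c0` and the physical
#'   constants).
#' @param duration_h Simulated time, hours.
#' @param record_dt_h Recording grid spacing, hours.
#' @param same_color_p Background adhesion probability for same-color
#'   encounters (default 0).
#' @param seed Integer seed; the simulation is reproducible under a fixed
#'   seed and leaves the global RNG untouched.
#' @return List with `od_trace` (an [od_series()]), `cluster_sizes` (data
#'   frame of size counts at the final time), `n_clusters` (per grid
#'   point), `truth` (list echoing `p` and the implied `k_od`).
#' @export
simulate_aggregation <- function(n_cells_per_color, p,
                                 model = aggregation_model(),
                                 duration_h = 1, record_dt_h = 1 / 60,
                                 same_color_p = 0, seed = 1) {
  stopifnot(n_cells_per_color >= 100, p >= 0, p <= 1, same_color_p >= 0)
  n <- as.integer(n_cells_per_color)
  k_od <- probability_to_rate(p, model)
  k_same <- probability_to_rate(same_color_p, model)
  odu <- model$c0 / n            # OD units contributed by one cluster
  lambda <- k_od * odu           # per hetero pair, per hour
  lambda_same <- k_same * odu

  # cluster state: sizes + composition class (1 pure red, 2 pure green,
  # 3 mixed); membership tracked as index vectors per class
  sizes <- rep(1L, 2L * n)
  classes <- rep(c(1L, 2L), each = n)
  alive <- rep(TRUE, 2L * n)

  grid <- seq(0, duration_h, by = record_dt_h)
  n_clusters_rec <- integer(length(grid))

  withr::with_seed(seed, {
    t_now <- 0
    gi <- 1L
    repeat {
      nR <- sum(alive & classes == 1L)
      nG <- sum(alive & classes == 2L)
      nM <- sum(alive & classes == 3L)
      pairs_het <- nR * nG + nM * (nR + nG) + nM * (nM - 1) / 2
      pairs_same <- nR * (nR - 1) / 2 + nG * (nG - 1) / 2
      rate <- lambda * pairs_het + lambda_same * pairs_same
      t_next <- if (rate > 0) t_now + stats::rexp(1, rate) else Inf
      while (gi <= length(grid) && grid[gi] < min(t_next, duration_h) + 1e-12) {
        n_clusters_rec[gi] <- nR + nG + nM
        gi <- gi + 1L
      }
      if (t_next > duration_h || rate == 0) break
      t_now <- t_next
      # choose the reacting pair category, then uniform clusters within it
      w <- c(lambda * nR * nG, lambda * nM * nR, lambda * nM * nG,
             lambda * nM * (nM - 1) / 2,
             lambda_same * nR * (nR - 1) / 2,
             lambda_same * nG * (nG - 1) / 2)
      cat_pair <- sample.int(6L, 1L, prob = w)
      pick <- function(cl, exclude = 0L) {
        cand <- which(alive & classes == cl)
        cand <- setdiff(cand, exclude)
        if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
      }
      ij <- switch(cat_pair,
        c(pick(1L), pick(2L)),
        c(pick(3L), pick(1L)),
        c(pick(3L), pick(2L)),
        { a <- pick(3L); c(a, pick(3L, exclude = a)) },
        { a <- pick(1L); c(a, pick(1L, exclude = a)) },
        { a <- pick(2L); c(a, pick(2L, exclude = a)) })
      i <- ij[1]; j <- ij[2]
      sizes[i] <- sizes[i] + sizes[j]
      classes[i] <- if (classes[i] == classes[j]) classes[i] else 3L
      alive[j] <- FALSE
    }
    while (gi <= length(grid)) {
      n_clusters_rec[gi] <- sum(alive)
      gi <- gi + 1L
    }
  })

  trace <- od_series(sample_id = sprintf("sim_p%.4g_seed%d", p, seed),
                     condition = sprintf("p=%.4g", p), replicate = 1L,
                     times = grid, ods = n_clusters_rec * odu)
  final_sizes <- sizes[alive]
  list(od_trace = trace,
       cluster_sizes = as.data.frame(table(size = final_sizes),
                                     stringsAsFactors = FALSE),
       n_clusters = n_clusters_rec,
       total_cells = sum(final_sizes),
       truth = list(p = p, k_od = k_od, c0 = model$c0,
                    n_cells_per_color = n, seed = seed))
}
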