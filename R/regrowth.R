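#' Fitted growth-model parameters
#'
#' @return A list of class `growth_fit` with fields `model` (`"exponential"`
#'   or `"logistic"`), `r` (growth rate, per hour), `od0` (back-extrapolated
#'   initial OD600 -- the proxy for the initial active population), `k`
#'   (carrying capacity OD600, logistic only, else `NA`), `r_squared`,
#'   `window` (`c(t_start, t_end)` hours), `n_points`, `t0` (first time point
#'   of the fitting window) and `accepted` (logical QC flag: `r_squared >=
#'   0.99` by default).
#' @keywords internal
#' @name growth_fit
NULL

new_growth_fit <- function(model, r, od0, k, r_squared, window, n_points, t0,
                           accepted, sample_id = NA_character_) {
  structure(list(model = model, r = r, od0 = od0, k = k,
                 r_squared = r_squared, window = window, n_points = n_points,
                 t0 = t0, accepted = accepted, sample_id = sample_id),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit:%s> r = %.4g /h, od0 = %.4g%s, r2 = %.5f (%s), window %.2f-%.2f h, n = %d\n",
    x$model, x$r, x$od0,
    if (!is.na(x$k)) sprintf(", k = %.4g", x$k) else "",
    x$r_squared, if (x$accepted) "accepted" else "REJECTED",
    x$window[1], x$window[2], x$n_points))
  invisible(x)
}

r_squared_of <- function(fit) {
  # noise-free fixtures trip summary.lm's "essentially perfect fit" warning
  s <- suppressWarnings(summary(fit))
  as.numeric(s$r.squared)
}

# Default exponential-phase window: contiguous sub-windows of points with OD
# between the detection floor and 50% of the series maximum are scored by
# the r^2 of their log-linear fit; the longest window whose misfit (1 - r^2)
# is within a factor `misfit_slack` of the best candidate's misfit is
# selected. Two safeguards make the rule behave across noise levels:
# sub-windows shorter than half their parent run are not candidates
# (trimming is meant to drop a lag plateau or saturation shoulder, not to
# re-pick the phase from a lucky handful of points), and the factor-based
# band adapts to the data — on noise-free data the best misfit is ~0, so a
# kink-contaminated window is excluded and the pure exponential stretch is
# returned exactly, while on noisy data long windows score best and the
# full usable run is kept. O(m^2) via prefix sums.
select_exponential_window <- function(series, floor, min_points = 4L,
                                      misfit_slack = 10) {
  usable <- series$ods >= floor & series$ods <= 0.5 * max(series$ods)
  runs <- rle(usable)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values & runs$lengths >= min_points)
  if (length(cand) == 0) return(NULL)
  windows <- list()
  for (j in cand) {
    idx <- starts[j]:ends[j]
    t <- series$times[idx]
    y <- log(series$ods[idx])
    m <- length(idx)
    ct <- cumsum(c(0, t)); cy <- cumsum(c(0, y))
    ctt <- cumsum(c(0, t^2)); cyy <- cumsum(c(0, y^2))
    cty <- cumsum(c(0, t * y))
    min_len <- max(min_points, ceiling(m / 2))
    for (a in 1:(m - min_len + 1L)) {
      for (b in (a + min_len - 1L):m) {
        n <- b - a + 1L
        st <- ct[b + 1] - ct[a]; sy <- cy[b + 1] - cy[a]
        stt <- ctt[b + 1] - ctt[a]; syy <- cyy[b + 1] - cyy[a]
        sty <- cty[b + 1] - cty[a]
        var_t <- stt - st^2 / n
        var_y <- syy - sy^2 / n
        cov_ty <- sty - st * sy / n
        r2 <- if (var_y <= 0 || var_t <= 0) 0 else cov_ty^2 / (var_t * var_y)
        windows[[length(windows) + 1L]] <-
          c(start = idx[a], end = idx[b], n = n, r2 = min(r2, 1))
      }
    }
  }
  w <- do.call(rbind, windows)
  best_misfit <- min(1 - w[, "r2"])
  ok <- (1 - w[, "r2"]) <= misfit_slack * best_misfit + 1e-12
  w <- w[ok, , drop = FALSE]
  pick <- order(-w[, "n"], -w[, "r2"], w[, "start"])[1]
  w[pick, "start"]:w[pick, "end"]
}

#' Fit an exponential growth model by log-linear regression
#'
#' Ordinary least squares of `ln OD` on time over the exponential phase;
#' the slope is the growth rate `r` (per hour) and the intercept is
#' `ln(od0)`, so `od0` is the back-extrapolated initial OD600. Any extra lag
#' induced by a treatment is deliberately not modeled: it depresses `od0`
#' and therefore the downstream viability estimate, which is the assay's
#' intended stringency.
#'
#' Fits with `r_squared` below `r2_threshold` (default 0.99) are flagged
#' `accepted = FALSE`, not errored; [viability_from_regrowth()] refuses
#' rejected fits unless overridden.
#'
#' @param series An [od_series()].
#' @param window Optional `c(t_start, t_end)` in hours. When `NULL`, the
#'   window is chosen automatically: the contiguous run of points with OD
#'   between `floor` and 50% of the series maximum that maximizes r^2,
#'   subject to at least 4 points.
#' @param floor Detection floor OD; points below it never enter the
#'   automatic window.
#' @param r2_threshold QC threshold on the regression r^2.
#' @return A `growth_fit` with `model = "exponential"`.
#' @export
fit_exponential <- function(series, window = NULL, floor = 0.01,
                            r2_threshold = 0.99) {
  stopifnot(inherits(series, "od_series"))
  if (is.null(window)) {
    idx <- select_exponential_window(series, floor)
    if (is.null(idx))
      stop("insufficient data: no contiguous exponential-phase window with ",
           ">= 4 points above the detection floor", call. = FALSE)
  } else {
    idx <- which(series$times >= window[1] & series$times <= window[2])
    if (length(idx) < 4L)
      stop("insufficient data: fewer than 4 points in the fitting window",
           call. = FALSE)
    if (any(series$ods[idx] <= 0))
      stop("OD <= 0 inside the fitting window; cannot take logs",
           call. = FALSE)
  }
  t <- series$times[idx]
  y <- log(series$ods[idx])
  fit <- stats::lm(y ~ t)
  r <- unname(stats::coef(fit)[2])
  od0 <- exp(unname(stats::coef(fit)[1]))
  r2 <- r_squared_of(fit)
  new_growth_fit("exponential", r = r, od0 = od0, k = NA_real_,
                 r_squared = r2, window = range(t), n_points = length(idx),
                 t0 = t[1], accepted = r2 >= r2_threshold && r > 0,
                 sample_id = series$sample_id)
}

#' Fit a logistic growth model by the per-capita difference regression
#'
#' Linearization of the logistic equation: the per-capita growth rate
#' `(dOD/dt)/OD = r (1 - OD/k)` is linear in OD, so regressing the
#' finite-difference relative change against OD yields `r` as the intercept
#' and `k = -intercept/slope` from the slope. The derivative is estimated
#' with centered differences by default (second-order accurate); a forward
#' mode is available for comparison. `od0` is then obtained by feeding the
#' first fitted data point through [back_extrapolate_od0()].
#'
#' @param series An [od_series()] spanning enough of the sigmoid (max OD at
#'   least half the fitted plateau; warned otherwise).
#' @param r2_threshold QC threshold on the linearization r^2.
#' @param differences `"centered"` or `"forward"` finite differences.
#' @return A `growth_fit` with `model = "logistic"`.
#' @export
fit_logistic_difference <- function(series, r2_threshold = 0.99,
                                    differences = c("centered", "forward")) {
  stopifnot(inherits(series, "od_series"))
  differences <- match.arg(differences)
  t <- series$times
  od <- series$ods
  n <- length(t)
  if (n < 5L)
    stop("insufficient data: logistic difference fit needs >= 5 points",
         call. = FALSE)
  if (any(od <= 0))
    stop("OD <= 0 in series; cannot form relative changes", call. = FALSE)
  if (differences == "centered") {
    i <- 2:(n - 1)
    g <- (od[i + 1] - od[i - 1]) / (t[i + 1] - t[i - 1]) / od[i]
    x <- od[i]
  } else {
    i <- 1:(n - 1)
    g <- (od[i + 1] - od[i]) / (t[i + 1] - t[i]) / od[i]
    x <- od[i]
  }
  if (stats::sd(x) == 0)
    stop("fit failure: constant OD series", call. = FALSE)
  fit <- stats::lm(g ~ x)
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  r <- intercept
  k <- -intercept / slope
  if (!is.finite(r) || !is.finite(k) || r <= 0 || k <= 0)
    stop(sprintf(
      "fit failure: non-positive logistic parameters (r = %.4g, k = %.4g)",
      r, k), call. = FALSE)
  r2 <- r_squared_of(fit)
  if (max(od) < 0.5 * k)
    warning("series covers less than half the fitted plateau; ",
            "carrying-capacity estimate is poorly constrained",
            call. = FALSE)
  od0 <- back_extrapolate_od0(r, k, od_t0 = od[1], t0 = t[1])
  new_growth_fit("logistic", r = r, od0 = od0, k = k, r_squared = r2,
                 window = range(t), n_points = n, t0 = t[1],
                 accepted = r2 >= r2_threshold,
                 sample_id = series$sample_id)
}

#' Back-extrapolate the initial OD from logistic parameters
#'
#' Analytical inversion of the logistic solution:
#' `od0 = k * OD(t0) / (OD(t0) + (k - OD(t0)) * exp(r * t0))`.
#' For `k` much larger than the observed OD this reduces to the exponential
#' back-extrapolation `OD(t0) * exp(-r * t0)`.
#'
#' @param r Growth rate, per hour (> 0).
#' @param k Carrying capacity, OD600 units.
#' @param od_t0 Observed OD at time `t0`; must satisfy `0 < od_t0 < k`.
#' @param t0 Time of the observation, hours (>= 0).
#' @return The initial OD600, `<= od_t0`.
#' @export
back_extrapolate_od0 <- function(r, k, od_t0, t0) {
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  if (t0 < 0) stop("t0 must be >= 0", call. = FALSE)
  if (od_t0 <= 0) stop("od_t0 must be > 0", call. = FALSE)
  if (od_t0 >= k)
    stop("od_t0 must be below the carrying capacity k", call. = FALSE)
  k * od_t0 / (od_t0 + (k - od_t0) * exp(r * t0))
}

#' Forward-propagate an initial OD through the logistic solution
#'
#' Exact inverse of [back_extrapolate_od0()]; used for consistency checks
#' and by the synthetic growth generator.
#'
#' @inheritParams back_extrapolate_od0
#' @param od0 Initial OD600.
#' @param t Time, hours.
#' @return OD600 at time `t`.
#' @export
logistic_od <- function(od0, r, k, t) {
  k * od0 * exp(r * t) / (k + od0 * (exp(r * t) - 1))
}

check_fits <- function(fits, arm, allow_rejected) {
  for (f in fits) {
    if (!inherits(f, "growth_fit"))
      stop("all elements of `", arm, "` must be growth_fit objects",
           call. = FALSE)
    if (!f$accepted && !allow_rejected)
      stop("fit for sample '", f$sample_id, "' (", arm, ") was rejected by ",
           "QC (r^2 < threshold); pass allow_rejected = TRUE to override",
           call. = FALSE)
  }
  invisible(NULL)
}

#' Viability from paired regrowth fits
#'
#' The regrowth viability estimate: for each biological replicate, the ratio
#' of the treated sample's back-extrapolated initial OD600 to its paired
#' untreated control's. Replicates are paired by position in the two lists.
#' The mean ratio is the condition's viability (1.0 = control-equivalent),
#' with SEM across replicates and a one-sided one-sample t test against 1
#' (alternative "less": treatments can only be scored as reducing activity).
#'
#' @param treated,controls Lists of accepted `growth_fit` objects of equal
#'   length, index-paired by biological replicate.
#' @param condition Label stored on the estimate.
#' @param allow_rejected Include fits that failed the r^2 QC (default FALSE).
#' @return A list of class `viability_estimate`: `condition`, `viability`,
#'   `per_replicate`, `sem`, `test` (a `test_result`).
#' @seealso [adjust_family()] to BH-correct across conditions.
#' @export
viability_from_regrowth <- function(treated, controls, condition = NA_character_,
                                    allow_rejected = FALSE) {
  if (length(treated) != length(controls) || length(treated) == 0)
    stop("pairing error: `treated` and `controls` must be non-empty lists ",
         "of equal length (index-paired replicates)", call. = FALSE)
  check_fits(treated, "treated", allow_rejected)
  check_fits(controls, "controls", allow_rejected)
  ratios <- vapply(seq_along(treated), function(i) {
    treated[[i]]$od0 / controls[[i]]$od0
  }, numeric(1))
  n <- length(ratios)
  structure(list(
    condition = condition,
    viability = mean(ratios),
    per_replicate = ratios,
    sem = if (n > 1) stats::sd(ratios) / sqrt(n) else 0,
    # noise-free fixtures give exactly constant ratios != 1, where the t
    # test is undefined; report the estimate without a test in that case
    test = if (n >= 2) tryCatch(one_sample_t_one_sided(ratios, 1, "less"),
                                error = function(e) NULL) else NULL
  ), class = "viability_estimate")
}

#' @export
print.viability_estimate <- function(x, ...) {
  cat(sprintf("<viability_estimate> condition %s: %.3f +/- %.3f SEM (n = %d)",
              x$condition, x$viability, x$sem, length(x$per_replicate)))
  if (!is.null(x$test)) cat(sprintf(", p(less than 1) = %.4g", x$test$p_value))
  cat("\n")
  invisible(x)
}

#' Test for a treatment effect on the growth rate
#'
#' One-sided one-sample t test on per-replicate growth-rate ratios
#' `r_treated / r_control` against 1 (alternative "less"), replicates paired
#' by position.
#'
#' @inheritParams viability_from_regrowth
#' @return A `test_result`.
#' @export
growth_rate_effect <- function(treated, controls, allow_rejected = FALSE) {
  if (length(treated) != length(controls) || length(treated) < 2)
    stop("degenerate input: need >= 2 paired replicates", call. = FALSE)
  check_fits(treated, "treated", allow_rejected)
  check_fits(controls, "controls", allow_rejected)
  ratios <- vapply(seq_along(treated), function(i) {
    treated[[i]]$r / controls[[i]]$r
  }, numeric(1))
  one_sample_t_one_sided(ratios, 1, "less")
}
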