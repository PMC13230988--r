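#' Clonal lineage trace of area and mean fluorescence
#'
#' Time course of a growing clonal patch of surface-labeled cells: segmented
#' lineage area and mean fluorescence per unit area at each imaging time
#' point. Transient area dips below 5% are tolerated with a warning (image
#' segmentation jitter); larger shrinkage is rejected.
#'
#' @param lineage_id Character scalar.
#' @param timepoints Hours, strictly increasing, length >= 3.
#' @param areas Lineage areas, um^2, > 0.
#' @param mean_fluorescences Mean fluorescence per unit area, a.u., > 0.
#' @param replicate Biological replicate number.
#' @return A list of class `lineage_trace`.
#' @export
lineage_trace <- function(lineage_id, timepoints, areas, mean_fluorescences,
                          replicate = 1L) {
  timepoints <- as.numeric(timepoints)
  areas <- as.numeric(areas)
  mean_fluorescences <- as.numeric(mean_fluorescences)
  n <- length(timepoints)
  if (n < 3L) stop("lineage trace needs >= 3 timepoints", call. = FALSE)
  if (length(areas) != n || length(mean_fluorescences) != n)
    stop("timepoints, areas and mean_fluorescences must have equal length",
         call. = FALSE)
  if (is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be strictly increasing", call. = FALSE)
  if (any(areas <= 0)) stop("areas must be > 0", call. = FALSE)
  rel_dip <- diff(areas) / areas[-n]
  if (any(rel_dip < -0.05))
    stop("lineage area shrinks by more than 5% between timepoints",
         call. = FALSE)
  if (any(rel_dip < 0))
    warning("transient area dip (< 5%) in lineage ", lineage_id,
            call. = FALSE)
  structure(list(lineage_id = as.character(lineage_id),
                 timepoints = timepoints, areas = areas,
                 mean_fluorescences = mean_fluorescences,
                 replicate = as.integer(replicate)),
            class = "lineage_trace")
}

#' Number of area doublings
#'
#' `d = log2(area / initial_area)`. Negative values (shrinkage) are allowed
#' but flagged with a warning.
#'
#' @param area,initial_area Areas, um^2, both > 0. `area` may be a vector.
#' @return Doublings, dimensionless.
#' @export
doublings <- function(area, initial_area) {
  if (any(area <= 0) || initial_area <= 0)
    stop("areas must be > 0", call. = FALSE)
  d <- log2(area / initial_area)
  if (any(d < 0))
    warning("negative doublings: area below the initial area (shrinkage)",
            call. = FALSE)
  d
}

#' Fit the per-doubling fluorescence retention fraction
#'
#' Fits `A(d) = a0 * f^d` to a lineage's mean fluorescence versus area
#' doublings by log-linear least squares (regress `ln A` on `d`; `f =
#' exp(slope)`), pooling all timepoints of the lineage. With an exactly
#' conserved total label, mean fluorescence is inversely proportional to
#' area and `f = 0.5`; independent per-doubling losses (e.g., bleaching)
#' multiply into `f`.
#'
#' @param trace A [lineage_trace()] spanning at least one full doubling.
#' @param f_flag_above Retention values above this are flagged (not
#'   rejected) as unphysical; default 1.05.
#' @return A list of class `retention_fit`: `f`, `a0`, `r_squared`,
#'   `doubling_span`, `flagged`, `lineage_id`.
#' @export
fit_retention <- function(trace, f_flag_above = 1.05) {
  stopifnot(inherits(trace, "lineage_trace"))
  if (any(trace$mean_fluorescences <= 0))
    stop("mean fluorescence must be > 0 for the log-linear fit",
         call. = FALSE)
  d <- suppressWarnings(doublings(trace$areas, trace$areas[1]))
  span <- max(d) - min(d)
  if (span < 1)
    stop("insufficient dynamics: lineage spans ", signif(span, 3),
         " doublings; need >= 1", call. = FALSE)
  fit <- stats::lm(log(trace$mean_fluorescences) ~ d)
  f <- exp(unname(stats::coef(fit)[2]))
  a0 <- exp(unname(stats::coef(fit)[1]))
  flagged <- f > f_flag_above
  if (flagged)
    warning("fitted retention f = ", signif(f, 4),
            " exceeds ", f_flag_above, " (gain with growth is unphysical)",
            call. = FALSE)
  structure(list(f = f, a0 = a0, r_squared = r_squared_of(fit),
                 doubling_span = span, flagged = flagged,
                 lineage_id = trace$lineage_id),
            class = "retention_fit")
}

#' @export
print.retention_fit <- function(x, ...) {
  cat(sprintf(
    "<retention_fit> %s: f = %.4g per doubling (a0 = %.4g, r2 = %.4f, span %.2f doublings)\n",
    x$lineage_id, x$f, x$a0, x$r_squared, x$doubling_span))
  invisible(x)
}

#' Five-number summary of retention across lineages
#'
#' @param fits List of [fit_retention()] results (>= 2).
#' @return List with `median`, `q1`, `q3`, `min`, `max`, `n` and the raw
#'   `f` values.
#' @export
summarize_retention <- function(fits) {
  stopifnot(all(vapply(fits, inherits, logical(1), "retention_fit")))
  if (length(fits) < 2L)
    stop("need >= 2 retention fits to summarize", call. = FALSE)
  f <- vapply(fits, function(x) x$f, numeric(1))
  q <- unname(stats::quantile(f, c(0.25, 0.5, 0.75)))
  list(median = q[2], q1 = q[1], q3 = q[3], min = min(f), max = max(f),
       n = length(f), f_values = f)
}
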