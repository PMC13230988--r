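#' Labeled cell-centroid point set
#'
#' Validates a table of segmented cell centroids carrying a two-color label
#' and an aggregate identifier. Coordinates are in micrometres; `z` is
#' optional (individual confocal slices are 2D).
#'
#' @param points Data frame with columns `x`, `y`, optional `z`, `color`
#'   (`"red"`/`"green"`) and `aggregate_id`.
#' @param replicate Biological replicate number.
#' @param condition Condition label.
#' @return A list of class `labeled_point_set`.
#' @export
labeled_point_set <- function(points, replicate = 1L,
                              condition = NA_character_) {
  stopifnot(is.data.frame(points))
  for (col in c("x", "y", "color", "aggregate_id"))
    if (!col %in% names(points))
      stop("missing required column: ", col, call. = FALSE)
  if (nrow(points) == 0) stop("empty point set", call. = FALSE)
  coords <- c("x", "y", if ("z" %in% names(points)) "z")
  if (any(!is.finite(as.matrix(points[coords]))))
    stop("coordinates must be finite", call. = FALSE)
  if (!all(points$color %in% c("red", "green")))
    stop("color must be 'red' or 'green'", call. = FALSE)
  structure(list(points = points, replicate = as.integer(replicate),
                 condition = condition, dims = length(coords)),
            class = "labeled_point_set")
}

nn_one <- function(coords) {
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  # ties in nearest distance break to the lowest point index (deterministic)
  apply(d, 1, which.min)
}

# nearest-neighbor structure per aggregate (geometry only, color-free, so
# permutation nulls can reuse it): list of global index vectors and, for
# each, the within-aggregate nearest neighbor as a local index
nn_structure <- function(pts, warn_singletons = TRUE) {
  df <- pts$points
  coords <- c("x", "y", if ("z" %in% names(df)) "z")
  split_idx <- split(seq_len(nrow(df)), df$aggregate_id)
  singletons <- names(split_idx)[lengths(split_idx) < 2L]
  if (length(singletons) > 0) {
    if (warn_singletons)
      warning("excluding ", length(singletons),
              " aggregate(s) with a single point: ",
              paste(utils::head(singletons, 5), collapse = ", "),
              call. = FALSE)
    split_idx <- split_idx[lengths(split_idx) >= 2L]
  }
  if (length(split_idx) == 0)
    stop("no aggregate with >= 2 points", call. = FALSE)
  nn <- lapply(split_idx, function(idx)
    nn_one(as.matrix(df[idx, coords, drop = FALSE])))
  list(split_idx = split_idx, nn = nn)
}

pooled_p_rg <- function(struct, colors) {
  frac <- vapply(seq_along(struct$split_idx), function(a) {
    idx <- struct$split_idx[[a]]
    cols <- colors[idx]
    mean(cols[struct$nn[[a]]] != cols)
  }, numeric(1))
  names(frac) <- names(struct$split_idx)
  n_cells <- lengths(struct$split_idx)
  list(p_rg = sum(frac * n_cells) / sum(n_cells), per_aggregate = frac,
       n_cells = n_cells)
}

#' Fraction of cells whose nearest neighbor has the opposite color
#'
#' For every cell, the nearest neighbor within the same aggregate is found
#' by Euclidean distance (each cell contributes exactly one directed
#' cell -> neighbor pair; distance ties break to the lowest point index).
#' `p_rg` is the fraction of cells whose nearest neighbor carries the
#' opposite fluorescent label, computed per aggregate and pooled with
#' cell-count weights. Under random, independent, balanced labels the
#' expectation is 0.5; strict complement-driven assembly pushes it higher.
#'
#' @param pts A [labeled_point_set()]. Aggregates with a single point are
#'   excluded with a warning.
#' @return A list of class `mixing_result`: `p_rg` (pooled), `per_aggregate`
#'   (named vector of per-aggregate fractions), `n_cells` (per aggregate).
#' @export
opposite_color_nn_fraction <- function(pts) {
  stopifnot(inherits(pts, "labeled_point_set"))
  struct <- nn_structure(pts)
  structure(pooled_p_rg(struct, pts$points$color), class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat(sprintf("<mixing_result> p_rg = %.3f over %d aggregate(s), %d cells\n",
              x$p_rg, length(x$per_aggregate), sum(x$n_cells)))
  invisible(x)
}

#' Permutation null for the opposite-color mixing fraction
#'
#' Shuffles color labels within each aggregate (conditioning on the
#' observed per-aggregate color counts, so the geometry and color balance
#' are preserved) and recomputes the pooled `p_rg`; returns the null mean
#' and a central 95% interval. Seeded and reproducible.
#'
#' @param pts A [labeled_point_set()].
#' @param n_permutations Number of label reshuffles (>= 100).
#' @param seed Integer RNG seed.
#' @return A list: `null_values`, `null_mean`, `null_interval`
#'   (2.5%/97.5% quantiles), `observed` (the unshuffled `p_rg`).
#' @export
permutation_null <- function(pts, n_permutations = 1000, seed = 1) {
  stopifnot(inherits(pts, "labeled_point_set"))
  if (n_permutations < 100)
    stop("n_permutations must be >= 100", call. = FALSE)
  struct <- nn_structure(pts)
  colors <- pts$points$color
  observed <- pooled_p_rg(struct, colors)$p_rg
  null_values <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      shuffled <- colors
      for (idx in struct$split_idx) {
        shuffled[idx] <- colors[idx][sample.int(length(idx))]
      }
      pooled_p_rg(struct, shuffled)$p_rg
    }, numeric(1))
  })
  list(null_values = null_values, null_mean = mean(null_values),
       null_interval = unname(stats::quantile(null_values,
                                              c(0.025, 0.975))),
       observed = observed)
}

#' Compare mixing fractions across conditions
#'
#' Replicate-level means are the unit of analysis. Condition A is tested
#' against the random expectation (two-sided one-sample t test against 0.5)
#' and against condition B (two-tailed Welch's unequal-variance t test).
#'
#' @param condition_a,condition_b Numeric vectors of replicate-level `p_rg`
#'   values (>= 2 replicates each).
#' @param random_expectation Null mixing fraction (default 0.5).
#' @return A list: `one_sample` (`test_result` vs the random expectation),
#'   `welch` (`test_result` between conditions), `mean_a`, `sem_a`,
#'   `mean_b`, `sem_b`.
#' @export
compare_mixing <- function(condition_a, condition_b,
                           random_expectation = 0.5) {
  a <- as.numeric(condition_a)
  b <- as.numeric(condition_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("degenerate input: need >= 2 replicates per condition",
         call. = FALSE)
  one_sample <- if (stats::sd(a) == 0 &&
                    isTRUE(all.equal(mean(a), random_expectation))) {
    test_result(0, length(a) - 1, 1, "two_sided")
  } else {
    tt <- stats::t.test(a, mu = random_expectation,
                        alternative = "two.sided")
    test_result(unname(tt$statistic), unname(tt$parameter),
                unname(tt$p.value), "two_sided")
  }
  list(one_sample = one_sample,
       welch = welch_t_two_sided(a, b),
       mean_a = mean(a), sem_a = stats::sd(a) / sqrt(length(a)),
       mean_b = mean(b), sem_b = stats::sd(b) / sqrt(length(b)))
}
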