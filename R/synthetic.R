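#' Seeded synthetic-data generators
#'
#' Every generator in this family emulates one input of the analysis
#' pipeline with a known ground truth, embedded in the returned object's
#' `truth` field, so that each fitting stage can be exercised end-to-end
#' without instrument data. All generators are deterministic under a fixed
#' seed and leave the global RNG state untouched.
#'
#' @name synthetic_data
#' @keywords internal
NULL

#' Generate paired treated/control regrowth curves
#'
#' Control curves follow the closed-form exponential or logistic model;
#' treated curves start at `od0_control * viability_true` (reduced initial
#' active population) and/or are delayed by `lag_h` (extra lag, implemented
#' as a time shift, which the downstream fit folds into a lower od0).
#' Measurement noise is multiplicative log-normal, the realistic model for
#' plate-reader OD, keeping readings positive.
#'
#' @param model `"exponential"` or `"logistic"`.
#' @param r Growth rate, per hour.
#' @param k Carrying capacity OD600 (logistic only).
#' @param od0_control Initial OD600 of the untreated control.
#' @param viability_true True fraction of active cells in the treated
#'   sample, in (0, 1.5].
#' @param lag_h Extra lag of the treated sample, hours.
#' @param noise_sd_log SD of the log-normal multiplicative noise.
#' @param n_replicates Number of paired biological replicates.
#' @param dt_h Sampling interval, hours.
#' @param horizon_h Last time point, hours.
#' @param seed Integer seed.
#' @return List with `control` and `treated` (lists of [od_series()],
#'   index-paired) and `truth`.
#' @export
gen_growth_curves <- function(model = c("exponential", "logistic"),
                              r = 0.7, k = 1.2, od0_control = 0.005,
                              viability_true = 1, lag_h = 0,
                              noise_sd_log = 0.02, n_replicates = 4,
                              dt_h = 0.25, horizon_h = 12, seed = 1) {
  model <- match.arg(model)
  stopifnot(r > 0, od0_control > 0, viability_true > 0,
            viability_true <= 1.5, lag_h >= 0, noise_sd_log >= 0)
  times <- seq(0, horizon_h, by = dt_h)
  mean_od <- function(od0, lag) {
    te <- pmax(times - lag, 0)
    if (model == "exponential") od0 * exp(r * te)
    else logistic_od(od0, r, k, te)
  }
  if (model == "exponential" && od0_control * exp(r * horizon_h) < 0.1)
    warning("horizon too short: control barely leaves the detection floor",
            call. = FALSE)
  make <- function(od0, lag, arm, rep) {
    mu <- mean_od(od0, lag)
    noisy <- mu * exp(stats::rnorm(length(mu), 0, noise_sd_log))
    od_series(sprintf("%s_rep%d", arm, rep), condition = arm,
              replicate = rep, times = times, ods = noisy,
              medium_class = if (model == "exponential") "minimal"
                             else "rich")
  }
  out <- withr::with_seed(seed, {
    list(
      control = lapply(seq_len(n_replicates), function(i)
        make(od0_control, 0, "control", i)),
      treated = lapply(seq_len(n_replicates), function(i)
        make(od0_control * viability_true, lag_h, "treated", i))
    )
  })
  out$truth <- list(model = model, r = r, k = if (model == "logistic") k
                    else NA, od0_control = od0_control,
                    viability_true = viability_true, lag_h = lag_h,
                    noise_sd_log = noise_sd_log, seed = seed)
  out
}

#' Generate a bimodal live/dead flow-cytometry event table
#'
#' Per-event intensities are log-normal mixtures: the red (dead-stain)
#' channel mixes a low-intensity live mode and a high-intensity dead mode;
#' the green (label) channel is unimodal. `meanlog`/`sdlog` are on the
#' natural-log scale as in [stats::rlnorm()].
#'
#' @param n_events Number of events (>= 100).
#' @param live_frac Fraction of live events in \[0, 1\].
#' @param live_red_meanlog,live_red_sdlog Red-channel log-normal parameters
#'   of the live mode.
#' @param dead_red_meanlog,dead_red_sdlog Red-channel parameters of the
#'   dead mode.
#' @param green_meanlog,green_sdlog Green-channel parameters.
#' @param sample_id Label for the table.
#' @param seed Integer seed.
#' @return A [flow_event_table()] with an extra `truth` attribute.
#' @export
gen_flow_events <- function(n_events = 10000, live_frac = 0.9,
                            live_red_meanlog = log(50),
                            live_red_sdlog = 0.4,
                            dead_red_meanlog = log(3000),
                            dead_red_sdlog = 0.4,
                            green_meanlog = log(500), green_sdlog = 0.5,
                            sample_id = "synthetic", seed = 1) {
  stopifnot(n_events >= 100, live_frac >= 0, live_frac <= 1)
  tab <- withr::with_seed(seed, {
    is_live <- stats::runif(n_events) < live_frac
    red <- ifelse(is_live,
                  stats::rlnorm(n_events, live_red_meanlog, live_red_sdlog),
                  stats::rlnorm(n_events, dead_red_meanlog, dead_red_sdlog))
    green <- stats::rlnorm(n_events, green_meanlog, green_sdlog)
    t <- flow_event_table(sample_id, green, red)
    t$truth <- list(live_frac_realized = mean(is_live),
                    live_frac = live_frac, seed = seed)
    t
  })
  tab
}

#' Generate a bead calibration table
#'
#' `mfi = blank + slope_true * count * (1 + eps)` with relative Gaussian
#' noise `eps ~ N(0, noise_frac)`. Defaults mimic a five-bead MESF kit.
#'
#' @param slope_true True conversion slope, a.u. per molecule.
#' @param blank Blank (non-modified bead) fluorescence, a.u.
#' @param molecule_counts Molecules per bead for each population (>= 3
#'   distinct values for a usable calibration).
#' @param noise_frac Relative noise SD.
#' @param seed Integer seed.
#' @return List with `bead_points` (data frame), `blank_mfi` and `truth`.
#' @export
gen_bead_set <- function(slope_true = 0.1, blank = 50,
                         molecule_counts = c(5e3, 2e4, 8e4, 3e5, 1e6),
                         noise_frac = 0, seed = 1) {
  molecule_counts <- as.numeric(molecule_counts)
  if (length(unique(molecule_counts)) < 2L)
    stop("need at least 2 distinct molecule counts", call. = FALSE)
  mfi <- withr::with_seed(seed, {
    blank + slope_true * molecule_counts *
      (1 + stats::rnorm(length(molecule_counts), 0, noise_frac))
  })
  list(bead_points = data.frame(molecules_per_bead = molecule_counts,
                                mfi = mfi),
       blank_mfi = blank,
       truth = list(slope_true = slope_true, blank = blank,
                    noise_frac = noise_frac, seed = seed))
}

#' Generate a sedimentation OD trace from the stochastic coagulation model
#'
#' Thin wrapper over [simulate_aggregation()] that adds optional Gaussian
#' read noise and echoes the ground truth.
#'
#' @param p_true True adhesion probability per encounter.
#' @param model An [aggregation_model()].
#' @param duration_h,record_dt_h Simulated span and recording grid, hours.
#' @param n_cells_per_color Cells per population.
#' @param read_noise_sd SD of additive Gaussian OD read noise (readings are
#'   clamped at 0).
#' @param seed Integer seed.
#' @return List with `od_trace` (an [od_series()]) and `truth`.
#' @export
gen_aggregation_od <- function(p_true, model = aggregation_model(),
                               duration_h = 1, record_dt_h = 1 / 60,
                               n_cells_per_color = 2000,
                               read_noise_sd = 0, seed = 1) {
  sim <- simulate_aggregation(n_cells_per_color, p_true, model,
                              duration_h, record_dt_h, seed = seed)
  trace <- sim$od_trace
  if (read_noise_sd > 0) {
    trace$ods <- withr::with_seed(seed + 1L, {
      pmax(trace$ods + stats::rnorm(length(trace$ods), 0, read_noise_sd), 0)
    })
  }
  list(od_trace = trace,
       truth = c(sim$truth, list(read_noise_sd = read_noise_sd)))
}

#' Generate a two-color point aggregate
#'
#' Sequential attachment growth model for the spatial-mixing regimes. The
#' aggregate grows Eden-style on a square (2D) or cubic (3D) lattice with
#' spacing equal to one cell diameter: each new cell occupies a random
#' empty site adjacent to the cluster and binds a randomly chosen occupied
#' neighbor (its anchor). Positions are jittered by up to 10% of a cell
#' diameter, as segmented centroids are. The color rule distinguishes the
#' regimes:
#' * `hetero_only` -- the new cell always takes its anchor's opposite color
#'   (complementary strands on distinct populations: red only binds
#'   green), producing a strongly alternating, checkerboard-like packing;
#' * `both_strands` -- the new cell takes the anchor's opposite color with
#'   probability `hetero_bias` (default 0.75): when both populations carry
#'   both strands every contact can bind, yet complementary pairings still
#'   out-compete like pairings, giving mixing between the strict-complement
#'   regime and the random null;
#' * `random` -- positions uniform in a ball, labels i.i.d. fair coin.
#'
#' @param n_points Number of cells (>= 10).
#' @param regime `"hetero_only"`, `"both_strands"` or `"random"`.
#' @param dim 2 (confocal slice) or 3.
#' @param hetero_bias Probability that an attaching cell takes the opposite
#'   color of its anchor in the `both_strands` regime.
#' @param spacing_um Cell diameter used as the attachment distance.
#' @param aggregate_id,replicate,condition Metadata for the point set.
#' @param seed Integer seed.
#' @return A [labeled_point_set()] with a `truth` field.
#' @export
gen_point_aggregate <- function(n_points = 500,
                                regime = c("hetero_only", "both_strands",
                                           "random"),
                                dim = 2, hetero_bias = 0.75,
                                spacing_um = 1, aggregate_id = "agg1",
                                replicate = 1L, condition = NULL,
                                seed = 1) {
  regime <- match.arg(regime)
  stopifnot(n_points >= 10, dim %in% c(2, 3))
  if (is.null(condition)) condition <- regime
  rand_dir <- function() {
    v <- stats::rnorm(dim)
    v / sqrt(sum(v^2))
  }
  df <- withr::with_seed(seed, {
    if (regime == "random") {
      # uniform in a ball of radius set to match the packing of the
      # attachment model
      radius <- spacing_um * n_points^(1 / dim)
      xyz <- t(vapply(seq_len(n_points), function(i) {
        rand_dir() * radius * stats::runif(1)^(1 / dim)
      }, numeric(dim)))
      colors <- sample(c("red", "green"), n_points, replace = TRUE)
    } else {
      sites <- matrix(0L, n_points, dim)       # lattice coordinates
      colors <- character(n_points)
      colors[1] <- sample(c("red", "green"), 1)
      occupied <- new.env(hash = TRUE, parent = emptyenv())
      key <- function(s) paste(s, collapse = ",")
      assign(key(sites[1, ]), 1L, envir = occupied)
      steps <- rbind(diag(dim), -diag(dim))    # lattice neighbor offsets
      frontier <- lapply(seq_len(nrow(steps)), function(j) sites[1, ] + steps[j, ])
      for (i in 2:n_points) {
        repeat {
          pick <- sample.int(length(frontier), 1L)
          s <- frontier[[pick]]
          if (!exists(key(s), envir = occupied)) break
          frontier <- frontier[-pick]
        }
        frontier <- frontier[-pick]
        # anchor: random occupied lattice neighbor of the new site
        nb_idx <- integer(0)
        new_frontier <- list()
        for (j in seq_len(nrow(steps))) {
          nb <- s + steps[j, ]
          k <- key(nb)
          if (exists(k, envir = occupied)) {
            nb_idx <- c(nb_idx, get(k, envir = occupied))
          } else {
            new_frontier[[length(new_frontier) + 1L]] <- nb
          }
        }
        anchor <- nb_idx[sample.int(length(nb_idx), 1L)]
        opposite <- setdiff(c("red", "green"), colors[anchor])
        colors[i] <- if (regime == "hetero_only" ||
                         stats::runif(1) < hetero_bias) {
          opposite
        } else {
          colors[anchor]
        }
        sites[i, ] <- s
        assign(key(s), i, envir = occupied)
        frontier <- c(frontier, new_frontier)
      }
      xyz <- sites * spacing_um +
        matrix(stats::runif(n_points * dim, -0.1, 0.1) * spacing_um,
               n_points, dim)
    }
    d <- as.data.frame(xyz)
    names(d) <- c("x", "y", "z")[seq_len(dim)]
    d$color <- colors
    d$aggregate_id <- aggregate_id
    d
  })
  out <- labeled_point_set(df, replicate = replicate, condition = condition)
  out$truth <- list(regime = regime, n_points = n_points, dim = dim,
                    hetero_bias = if (regime == "both_strands") hetero_bias
                    else NA, seed = seed)
  out
}

#' Generate lineage area/fluorescence traces under label dilution
#'
#' Lineage area grows exponentially (one doubling per `doubling_time_h`);
#' mean fluorescence follows `a0 * f_true^d` with optional multiplicative
#' log-normal partitioning noise.
#'
#' @param f_true True retention fraction per doubling, in (0, 1].
#' @param n_doublings Doublings spanned by each trace (>= 1).
#' @param partition_noise SD of log-normal noise on mean fluorescence.
#' @param n_lineages Number of lineages.
#' @param n_timepoints Imaging time points per lineage.
#' @param a0 Initial mean fluorescence, a.u.
#' @param area0_um2 Initial lineage area, um^2.
#' @param doubling_time_h Area doubling time, hours.
#' @param seed Integer seed.
#' @return List with `traces` (list of [lineage_trace()]) and `truth`.
#' @export
gen_lineage <- function(f_true = 0.5, n_doublings = 3, partition_noise = 0,
                        n_lineages = 6, n_timepoints = 7, a0 = 1000,
                        area0_um2 = 4, doubling_time_h = 1, seed = 1) {
  stopifnot(f_true > 0, f_true <= 1, n_doublings >= 1, n_timepoints >= 3)
  times <- seq(0, n_doublings * doubling_time_h, length.out = n_timepoints)
  d <- times / doubling_time_h
  traces <- withr::with_seed(seed, {
    lapply(seq_len(n_lineages), function(i) {
      areas <- area0_um2 * 2^d
      fluor <- a0 * f_true^d *
        exp(stats::rnorm(n_timepoints, 0, partition_noise))
      lineage_trace(sprintf("lineage%d", i), times, areas, fluor,
                    replicate = i)
    })
  })
  list(traces = traces,
       truth = list(f_true = f_true, n_doublings = n_doublings,
                    partition_noise = partition_noise, seed = seed))
}
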