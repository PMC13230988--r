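#' Flow-cytometry event table
#'
#' Pre-gated per-event fluorescence intensities for one sample. Flow
#' practice records at least 10,000 meaningful events per sample; smaller
#' tables are accepted with a warning.
#'
#' @param sample_id Character scalar.
#' @param green_intensity,red_intensity Numeric vectors of per-event channel
#'   intensities (arbitrary units), equal length.
#' @return A list of class `flow_event_table` with fields `sample_id`,
#'   `green_intensity`, `red_intensity`, `n_events`.
#' @export
flow_event_table <- function(sample_id, green_intensity, red_intensity) {
  green_intensity <- as.numeric(green_intensity)
  red_intensity <- as.numeric(red_intensity)
  if (length(green_intensity) != length(red_intensity))
    stop("channel vectors must have equal length", call. = FALSE)
  n <- length(green_intensity)
  if (n < 1L) stop("event table must contain at least one event",
                   call. = FALSE)
  if (any(!is.finite(green_intensity)) || any(!is.finite(red_intensity)))
    stop("intensities must be finite", call. = FALSE)
  if (n < 10000L)
    warning("only ", n, " events recorded; fewer than the 10,000 ",
            "recommended for stable population statistics", call. = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 green_intensity = green_intensity,
                 red_intensity = red_intensity, n_events = n),
            class = "flow_event_table")
}

#' Read a flow event CSV (columns event_id, green_au, red_au)
#'
#' @param path CSV path.
#' @param sample_id Sample label; defaults to the file name.
#' @return A [flow_event_table()].
#' @export
read_flow_events <- function(path, sample_id = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("green_au", "red_au"))
    if (!col %in% names(df))
      stop("missing required column: ", col, call. = FALSE)
  flow_event_table(sample_id, df$green_au, df$red_au)
}

#' MESF bead calibration by background-subtracted linear regression
#'
#' Fits blank-subtracted bead mean fluorescence against the kit-reported
#' molecules-per-bead count by ordinary least squares with a free intercept.
#' The slope (a.u. per molecule) is the conversion factor between detector
#' units and Molecules of Equivalent Soluble Fluorochrome. A free intercept
#' is retained as a diagnostic: it should be small relative to the dimmest
#' bead's signal, and the calibration is flagged when it is not or when
#' r^2 < 0.99.
#'
#' @param bead_points Data frame with columns `molecules_per_bead` and
#'   `mfi` (one row per bead population; MESF kits typically provide five).
#' @param blank_mfi Measured fluorescence of non-modified beads.
#' @param r2_threshold QC threshold on the regression r^2.
#' @return A list of class `bead_calibration`: `slope` (a.u./molecule),
#'   `intercept`, `r_squared`, `blank_mfi`, `bead_points`, `accepted`,
#'   `flags` (character vector of QC notes).
#' @export
fit_mesf_calibration <- function(bead_points, blank_mfi, r2_threshold = 0.99) {
  stopifnot(is.data.frame(bead_points),
            all(c("molecules_per_bead", "mfi") %in% names(bead_points)))
  m <- as.numeric(bead_points$molecules_per_bead)
  y <- as.numeric(bead_points$mfi) - blank_mfi
  if (length(unique(m)) < 2L)
    stop("calibration error: need at least 2 distinct molecule counts",
         call. = FALSE)
  flags <- character(0)
  if (nrow(bead_points) < 3L) {
    warning("calibration from fewer than 3 bead populations; r^2 is not ",
            "informative", call. = FALSE)
    flags <- c(flags, "fewer than 3 bead points")
  }
  fit <- stats::lm(y ~ m)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0)
    stop("calibration error: non-positive slope", call. = FALSE)
  r2 <- r_squared_of(fit)
  lowest_signal <- min(abs(y))
  if (lowest_signal > 0 && abs(intercept) > 0.1 * lowest_signal)
    flags <- c(flags, "intercept large relative to dimmest bead signal")
  if (r2 < r2_threshold)
    flags <- c(flags, sprintf("r^2 = %.4f below %.2f", r2, r2_threshold))
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 blank_mfi = blank_mfi, bead_points = bead_points,
                 accepted = length(flags) == 0 ||
                   all(flags == "fewer than 3 bead points"),
                 flags = flags),
            class = "bead_calibration")
}

#' @export
print.bead_calibration <- function(x, ...) {
  cat(sprintf(
    "<bead_calibration> slope = %.4g a.u./molecule, intercept = %.4g, r2 = %.5f%s\n",
    x$slope, x$intercept, x$r_squared,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = "; "), "]")
    else ""))
  invisible(x)
}

#' Convert a background-subtracted intensity to molecules per cell
#'
#' `mesf = max(0, sample_mfi - background_mfi) / slope`, then divided by the
#' degree of labeling (fluorophores per conjugated molecule) to obtain the
#' molecule count. Because surface overcrowding quenches fluorescence
#' non-linearly, the count is a lower bound on the true surface loading and
#' carries `lower_bound_note = TRUE`.
#'
#' @param sample_mfi Mean fluorescence intensity of the sample, a.u.
#' @param background_mfi MFI of unmodified cells exposed to the fluorophore.
#' @param cal A [fit_mesf_calibration()] result.
#' @param degree_of_labeling Fluorophores per molecule, >= 1 (default 1).
#' @return A list of class `molecule_count_estimate`: `mesf`, `molecules`,
#'   `degree_of_labeling`, `lower_bound_note`.
#' @export
intensity_to_molecules <- function(sample_mfi, background_mfi, cal,
                                   degree_of_labeling = 1) {
  stopifnot(inherits(cal, "bead_calibration"))
  if (degree_of_labeling < 1)
    stop("degree_of_labeling must be >= 1", call. = FALSE)
  diff <- sample_mfi - background_mfi
  if (diff < 0) {
    warning("sample MFI below background; molecule count clamped to 0",
            call. = FALSE)
    diff <- 0
  }
  mesf <- diff / cal$slope
  structure(list(mesf = mesf, molecules = mesf / degree_of_labeling,
                 degree_of_labeling = degree_of_labeling,
                 lower_bound_note = TRUE),
            class = "molecule_count_estimate")
}

#' Population mean fluorescence intensity
#'
#' Arithmetic mean of background-subtracted event intensities (the reported
#' MFI statistic); a median mode is available for robustness to outliers.
#'
#' @param events A [flow_event_table()].
#' @param channel `"green"` or `"red"`.
#' @param background_mfi Scalar background to subtract (default 0).
#' @param statistic `"mean"` or `"median"`.
#' @return Numeric scalar, a.u.
#' @export
population_mfi <- function(events, channel = c("green", "red"),
                           background_mfi = 0,
                           statistic = c("mean", "median")) {
  channel <- match.arg(channel)
  statistic <- match.arg(statistic)
  x <- events[[paste0(channel, "_intensity")]] - background_mfi
  if (statistic == "mean") mean(x) else stats::median(x)
}

# Threshold at the minimum-density valley between the two largest modes of a
# kernel-density estimate of log10 intensity (dead-stain channels are
# bimodal on a log scale).
auto_stain_threshold <- function(intensities) {
  x <- log10(pmax(intensities, .Machine$double.eps))
  d <- stats::density(x, n = 512)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2L)
    stop("automatic threshold failed: intensity distribution is not bimodal",
         call. = FALSE)
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  valley_idx <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  10^d$x[valley_idx]
}

#' Viability from dead-cell stain thresholding
#'
#' Classifies events as viable (red intensity below the threshold) or
#' non-viable (above), then reports the sample's viable fraction relative
#' to the control's. Ratios above 1 are allowed and noted, not capped.
#'
#' @param events Sample [flow_event_table()].
#' @param control Control (untreated) event table.
#' @param threshold Red-intensity threshold, a.u. A user-supplied value is
#'   canonical; `NULL` requests the automatic mode, which places the
#'   threshold at the minimum-density valley between the two modes of a
#'   kernel-density estimate of the pooled log-intensities and labels the
#'   output accordingly.
#' @return A list of class `stain_viability`: `viability`,
#'   `viable_fraction_sample`, `viable_fraction_control`, `threshold`,
#'   `threshold_mode` (`"user"` or `"auto_kde_valley"`).
#' @export
stain_viability <- function(events, control, threshold = NULL) {
  stopifnot(inherits(events, "flow_event_table"),
            inherits(control, "flow_event_table"))
  mode <- "user"
  if (is.null(threshold)) {
    threshold <- auto_stain_threshold(c(events$red_intensity,
                                        control$red_intensity))
    mode <- "auto_kde_valley"
  } else {
    rng <- range(c(events$red_intensity, control$red_intensity))
    if (threshold < rng[1] || threshold > rng[2])
      stop("threshold ", threshold, " lies outside the observed intensity ",
           "range [", rng[1], ", ", rng[2], "]", call. = FALSE)
  }
  fs <- mean(events$red_intensity < threshold)
  fc <- mean(control$red_intensity < threshold)
  if (fc == 0)
    stop("division error: control viable fraction is 0", call. = FALSE)
  v <- fs / fc
  if (v > 1)
    message("stain viability ratio ", signif(v, 4),
            " exceeds 1 (sample cleaner than control); reported uncapped")
  structure(list(viability = v, viable_fraction_sample = fs,
                 viable_fraction_control = fc, threshold = threshold,
                 threshold_mode = mode),
            class = "stain_viability")
}

#' Cell geometry for surface dosimetry
#'
#' @param shape `"spherocylinder"` (rod) or `"sphere"`.
#' @param radius_um Cell radius, micrometres.
#' @param total_length_um Pole-to-pole length for the spherocylinder
#'   (>= 2 * radius). Defaults describe a typical 1-2 um rod: r = 0.5 um,
#'   L = 2 um.
#' @return A list of class `cell_geometry`.
#' @export
cell_geometry <- function(shape = c("spherocylinder", "sphere"),
                          radius_um = 0.5, total_length_um = 2) {
  shape <- match.arg(shape)
  if (radius_um <= 0) stop("radius must be > 0", call. = FALSE)
  if (shape == "spherocylinder" && total_length_um < 2 * radius_um)
    stop("total length must be >= 2 * radius for a spherocylinder",
         call. = FALSE)
  structure(list(shape = shape, radius_um = radius_um,
                 total_length_um = if (shape == "spherocylinder")
                   total_length_um else NA_real_),
            class = "cell_geometry")
}

cell_surface_area_um2 <- function(geometry) {
  r <- geometry$radius_um
  if (geometry$shape == "sphere") return(4 * pi * r^2)
  L <- geometry$total_length_um
  2 * pi * r * (L - 2 * r) + 4 * pi * r^2
}

#' Surface density of tethered molecules
#'
#' Divides the cell surface area (spherocylinder: cylinder side plus two
#' hemispherical caps, `2*pi*r*(L - 2r) + 4*pi*r^2`) by the molecule count.
#' The mean spacing between adjacent molecules is the square root of the
#' area per molecule.
#'
#' @param molecules Molecule count per cell (>= 1).
#' @param geometry A [cell_geometry()].
#' @return List with `area_per_molecule_nm2`, `mean_spacing_nm` and
#'   `surface_area_um2`.
#' @examples
#' surface_density(210000, cell_geometry())  # ~30 nm^2, ~5.5 nm spacing
#' @export
surface_density <- function(molecules, geometry = cell_geometry()) {
  stopifnot(inherits(geometry, "cell_geometry"))
  if (molecules < 1) stop("molecules must be >= 1", call. = FALSE)
  area_um2 <- cell_surface_area_um2(geometry)
  apm <- area_um2 * 1e6 / molecules   # um^2 -> nm^2
  list(area_per_molecule_nm2 = apm, mean_spacing_nm = sqrt(apm),
       surface_area_um2 = area_um2)
}

#' Bulk-equivalent molar concentration of surface-bound molecules
#'
#' Molarity that the surface-bound molecules would have if released into
#' solution: `molecules_per_cell * cells_per_ml_per_od * od600 * 1000 / N_A`
#' (the factor 1000 converts per-ml to per-litre). With the standard
#' assumption of 1e9 cells/ml at OD600 1, a population carrying 210,000
#' molecules per cell at OD 0.1 corresponds to about 35 nM.
#'
#' @param molecules_per_cell Molecule count per cell.
#' @param od600 Culture optical density.
#' @param cells_per_ml_per_od Cell density per ml per OD600 unit
#'   (default 1e9).
#' @return Molar concentration (mol/L).
#' @export
bulk_equivalent_concentration <- function(molecules_per_cell, od600,
                                          cells_per_ml_per_od = 1e9) {
  if (od600 <= 0 || cells_per_ml_per_od <= 0)
    stop("od600 and cells_per_ml_per_od must be > 0", call. = FALSE)
  if (molecules_per_cell < 0)
    stop("molecules_per_cell must be >= 0", call. = FALSE)
  molecules_per_cell * cells_per_ml_per_od * od600 * 1000 / 6.02214076e23
}
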