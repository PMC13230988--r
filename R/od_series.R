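#' Optical-density time series for one well/sample
#'
#' Container for a blank-corrected OD600 growth or sedimentation trace of a
#' single sample (one well, one biological replicate, one condition).
#' Times are stored in hours and sorted ascending; the OD vector is permuted
#' consistently with the sort.
#'
#' @param sample_id Character scalar identifying the sample.
#' @param condition Character scalar describing the treatment condition
#'   (e.g., crosslinker dose in mg/L).
#' @param replicate Integer biological replicate number (>= 1).
#' @param times Numeric vector of time points, hours.
#' @param ods Numeric vector of OD600 readings, same length as `times`.
#' @param medium_class `"minimal"` or `"rich"`; selects the default growth
#'   model downstream (exponential in minimal media, logistic in rich media).
#'
#' @return An object of class `od_series`: a list with the fields above,
#'   times strictly increasing.
#' @examples
#' s <- od_series("w1", "0", 1, times = c(0, 1, 2, 3),
#'                ods = 0.02 * exp(0.5 * c(0, 1, 2, 3)))
#' @export
od_series <- function(sample_id, condition, replicate, times, ods,
                      medium_class = c("minimal", "rich")) {
  medium_class <- match.arg(medium_class)
  sample_id <- as.character(sample_id)
  condition <- as.character(condition)
  replicate <- as.integer(replicate)
  times <- as.numeric(times)
  ods <- as.numeric(ods)
  if (length(replicate) != 1L || is.na(replicate) || replicate < 1L)
    stop("`replicate` must be a single integer >= 1", call. = FALSE)
  if (length(times) != length(ods))
    stop("`times` and `ods` must have the same length", call. = FALSE)
  if (length(times) < 1L)
    stop("series must contain at least one reading", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(ods)))
    stop("times and ods must be finite", call. = FALSE)
  if (any(ods < 0))
    stop("ods must be >= 0 after blank subtraction", call. = FALSE)
  ord <- order(times)
  times <- times[ord]
  ods <- ods[ord]
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing (duplicated time point?)",
         call. = FALSE)
  structure(
    list(sample_id = sample_id, condition = condition, replicate = replicate,
         times = times, ods = ods, medium_class = medium_class),
    class = "od_series"
  )
}

#' @export
print.od_series <- function(x, ...) {
  cat(sprintf(
    "<od_series> %s | condition %s | replicate %d | %d points, %.2f-%.2f h, OD %.4g-%.4g\n",
    x$sample_id, x$condition, x$replicate, length(x$times),
    min(x$times), max(x$times), min(x$ods), max(x$ods)))
  invisible(x)
}

#' Column mapping and unit configuration for OD table readers
#'
#' @param sample_id,condition,replicate,time,od Column names in the file.
#' @param time_unit Unit of the time column; converted to hours on read.
#' @param blank_condition Optional condition label designating blank wells.
#'   When given, the per-plate mean OD of all blank readings is subtracted
#'   from every non-blank reading (clamped at 0 with a warning); blank series
#'   are dropped from the result.
#' @param medium_class Medium class recorded on every parsed series.
#' @return A list of class `od_layout`.
#' @export
od_layout <- function(sample_id = "sample_id", condition = "condition",
                      replicate = "replicate", time = "time_h", od = "od600",
                      time_unit = c("hours", "minutes", "seconds"),
                      blank_condition = NULL,
                      medium_class = c("minimal", "rich")) {
  structure(
    list(sample_id = sample_id, condition = condition, replicate = replicate,
         time = time, od = od, time_unit = match.arg(time_unit),
         blank_condition = blank_condition,
         medium_class = match.arg(medium_class)),
    class = "od_layout"
  )
}

time_divisor <- function(unit) {
  switch(unit, hours = 1, minutes = 60, seconds = 3600)
}

#' Read a long-format OD600 table
#'
#' Parses a tidy CSV/TSV with one reading per row into a list of
#' [od_series()], one per (sample, condition, replicate) triple, times sorted
#' ascending. Delimiter is inferred from the file extension (`.tsv` ->
#' tab, otherwise comma).
#'
#' @param path Path to the file.
#' @param layout An [od_layout()] describing column names, time unit and
#'   optional blank condition.
#' @return A list of `od_series`.
#' @export
read_od_table <- function(path, layout = od_layout()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(layout$sample_id, layout$condition, layout$replicate,
              layout$time, layout$od)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  od_raw <- df[[layout$od]]
  od_num <- suppressWarnings(as.numeric(od_raw))
  bad <- which(is.na(od_num) & !is.na(od_raw))
  if (length(bad) > 0)
    stop("non-numeric OD value at row ", bad[1], ": '", od_raw[bad[1]], "'",
         call. = FALSE)
  t_num <- suppressWarnings(as.numeric(df[[layout$time]]))
  if (anyNA(t_num))
    stop("non-numeric time value at row ", which(is.na(t_num))[1],
         call. = FALSE)
  t_h <- t_num / time_divisor(layout$time_unit)

  cond <- as.character(df[[layout$condition]])
  blank_offset <- 0
  keep <- rep(TRUE, nrow(df))
  if (!is.null(layout$blank_condition)) {
    is_blank <- cond == layout$blank_condition
    if (!any(is_blank))
      stop("blank condition '", layout$blank_condition,
           "' not present in file", call. = FALSE)
    blank_offset <- mean(od_num[is_blank])
    keep <- !is_blank
  }
  od_corr <- od_num - blank_offset
  if (any(od_corr[keep] < 0)) {
    warning("blank subtraction produced negative OD; clamped at 0",
            call. = FALSE)
    od_corr[od_corr < 0] <- 0
  }

  key <- interaction(df[[layout$sample_id]], cond, df[[layout$replicate]],
                     drop = TRUE)
  out <- lapply(split(which(keep), droplevels(key[keep])), function(idx) {
    od_series(sample_id = df[[layout$sample_id]][idx[1]],
              condition = cond[idx[1]],
              replicate = df[[layout$replicate]][idx[1]],
              times = t_h[idx], ods = od_corr[idx],
              medium_class = layout$medium_class)
  })
  unname(out)
}

#' Write OD series back to a long-format CSV
#'
#' Inverse of [read_od_table()] under the default layout; numeric content
#' round-trips to full precision.
#'
#' @param series A list of `od_series` (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_od_table <- function(series, path) {
  if (inherits(series, "od_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(sample_id = s$sample_id, condition = s$condition,
               replicate = s$replicate, time_h = s$times, od600 = s$ods,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
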