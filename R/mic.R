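#' Minimum inhibitory concentration from an endpoint plate
#'
#' Endpoint broth-microdilution analysis: after incubation the final OD600
#' of each well is compared against a growth threshold, by default 10% of
#' the drug-free control's endpoint OD. The MIC is the lowest concentration
#' at which growth is suppressed *and* all higher concentrations are also
#' suppressed (monotone enforcement); isolated no-growth wells below a
#' growing well are treated as artifacts and flagged with a warning.
#'
#' Censoring: growth at every concentration yields `mic = NA` with
#' `censored = "> max"`; suppression already at the lowest non-zero
#' concentration yields that concentration with `censored = "<= min"` since
#' the true MIC may lie below the tested range.
#'
#' @param concentrations Ascending antibiotic concentrations, ug/ml,
#'   including 0 (the drug-free control).
#' @param final_ods Endpoint OD600 per concentration, same length.
#' @param threshold_frac Growth threshold as a fraction of the drug-free
#'   control OD (default 0.1).
#' @param min_control_od Minimum drug-free endpoint OD for the assay to be
#'   considered valid.
#' @param reference_mic Optional reference MIC (ug/ml) for fold-change
#'   reporting.
#' @return A list of class `mic_result`: `concentrations`, `final_ods`,
#'   `threshold`, `mic` (ug/ml or `NA` when right-censored), `censored`
#'   (`"none"`, `"> max"` or `"<= min"`), `non_monotone` (logical),
#'   `fold_change_vs_reference`.
#' @examples
#' mic_from_endpoint(c(0, 12.5, 25, 50, 100),
#'                   c(1.0, 0.9, 0.8, 0.05, 0.04))
#' @export
mic_from_endpoint <- function(concentrations, final_ods, threshold_frac = 0.1,
                              min_control_od = 0.1, reference_mic = NULL) {
  concentrations <- as.numeric(concentrations)
  final_ods <- as.numeric(final_ods)
  if (length(concentrations) != length(final_ods))
    stop("concentrations and final_ods must have the same length",
         call. = FALSE)
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly ascending", call. = FALSE)
  if (concentrations[1] != 0)
    stop("concentrations must include 0 (drug-free control)", call. = FALSE)
  control_od <- final_ods[1]
  if (control_od < min_control_od)
    stop("no-growth error: drug-free control OD ", control_od,
         " is below ", min_control_od, "; assay invalid", call. = FALSE)
  threshold <- threshold_frac * control_od

  conc <- concentrations[-1]
  suppressed <- final_ods[-1] < threshold
  m <- length(conc)
  # lowest concentration from which suppression holds all the way up
  all_above <- rev(cumprod(rev(suppressed))) == 1
  non_monotone <- any(suppressed & !all_above)
  if (non_monotone)
    warning("non-monotone plate: growth above a suppressed well; MIC raised ",
            "past the highest growing concentration", call. = FALSE)
  if (!any(all_above)) {
    mic <- NA_real_
    censored <- "> max"
  } else {
    mic <- conc[which(all_above)[1]]
    censored <- if (mic == conc[1]) "<= min" else "none"
  }
  fold <- if (!is.null(reference_mic) && !is.na(mic)) mic / reference_mic
          else NA_real_
  structure(list(concentrations = concentrations, final_ods = final_ods,
                 threshold = threshold, mic = mic, censored = censored,
                 non_monotone = non_monotone,
                 fold_change_vs_reference = fold),
            class = "mic_result")
}

#' @export
print.mic_result <- function(x, ...) {
  lab <- if (is.na(x$mic)) {
    sprintf("> %g ug/ml (right-censored)", max(x$concentrations))
  } else if (x$censored == "<= min") {
    sprintf("<= %g ug/ml (left-censored)", x$mic)
  } else sprintf("%g ug/ml", x$mic)
  cat("<mic_result> MIC", lab)
  if (!is.na(x$fold_change_vs_reference))
    cat(sprintf(", %.3g-fold vs reference", x$fold_change_vs_reference))
  cat("\n")
  invisible(x)
}
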