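#' Fractional flow change per outlet
#'
#' \eqn{\Delta Q = (Q_{healthy} - Q_{stroke}) / Q_{healthy}}: 0 for an
#' unchanged outlet, 1 when flow stops entirely.
#'
#' @param Q_healthy,Q_stroke outlet flows, ml/s (vectorised).
#' @return Dimensionless fraction.
#' @export
fractional_flow_change <- function(Q_healthy, Q_stroke) {
  if (any(Q_healthy <= 0)) {
    bad <- which(Q_healthy <= 0)
    stop("fractional_flow_change: undefined baseline (Q_healthy <= 0) at outlet(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  (Q_healthy - Q_stroke) / Q_healthy
}

#' Classify outlets by fractional flow change
#'
#' Pairs every pial outlet of a stroke simulation with the same outlet in
#' the healthy baseline (same network realization) and computes its
#' fractional flow change. An outlet is classified as infarcted when its
#' flow has dropped by at least the perfusion threshold (default 0.4,
#' i.e. 60% or less of its healthy flow remains); the tie is inclusive.
#'
#' @param baseline healthy `bf_result`.
#' @param stroke stroke `bf_result` on the same network realization.
#' @param config a [model_config()] (uses `infarct.threshold`).
#' @return Tibble: `node`, `territory`, `Q_healthy`, `Q_stroke`, `dQ`,
#'   `infarcted`.
#' @export
classify_outlets <- function(baseline, stroke, config = model_config()) {
  stopifnot(identical(baseline$outlets$node, stroke$outlets$node))
  dQ <- fractional_flow_change(baseline$outlets$flow_ml_s,
                               stroke$outlets$flow_ml_s)
  tibble::tibble(
    node = baseline$outlets$node,
    territory = baseline$outlets$territory,
    Q_healthy = baseline$outlets$flow_ml_s,
    Q_stroke = stroke$outlets$flow_ml_s,
    dQ = dQ,
    infarcted = dQ >= config$infarct$threshold
  )
}

#' Infarct volume from classified outlets
#'
#' Each pial outlet perfuses an equal share of the brain, so the infarct
#' volume is
#' \deqn{IV = V_{brain} \; \frac{N_{infarcted}}{N_{total}}.}
#'
#' @param outlet_changes either the tibble from [classify_outlets()] or a
#'   numeric vector of fractional flow changes.
#' @param config a [model_config()] (threshold, used when a numeric vector
#'   is supplied).
#' @param V_brain_ml brain volume, ml.
#' @param N_total total number of pial outlets; defaults to the number of
#'   classified outlets.
#' @return Infarct volume, ml.
#' @examples
#' infarct_volume(c(rep(0.8, 250), rep(0, 750)), V_brain_ml = 1390) # 347.5
#' @export
infarct_volume <- function(outlet_changes, config = model_config(),
                           V_brain_ml = 1390, N_total = NULL) {
  if (is.data.frame(outlet_changes)) {
    infarcted <- outlet_changes$infarcted
  } else {
    infarcted <- outlet_changes >= config$infarct$threshold
  }
  if (is.null(N_total)) N_total <- length(infarcted)
  V_brain_ml * sum(infarcted) / N_total
}

#' Clinical collateral-grade reference table
#'
#' Published reference values for the four clinical collateral grades:
#' patient counts and median final infarct volumes (with interquartile
#' range) from follow-up imaging of acute ischaemic stroke cohorts, and
#' the corresponding large-mesh model means reported alongside them. These
#' are the default calibration targets for
#' [calibrate_collateral_probability()]. They are reference values from
#' patient-scale studies: desk-scale synthetic networks are not expected
#' to reproduce them (their collateral conductance per territory pair
#' depends on mesh resolution), which is why calibration against them is
#' re-run per mesh rather than shipping fixed probabilities.
#'
#' @return Tibble: `grade`, `n_patients`, `median_infarct_ml`,
#'   `iqr_low_ml`, `iqr_high_ml`, `reference_model_mean_ml`.
#' @export
collateral_grade_targets <- function() {
  tibble::tibble(
    grade = c("absent", "poor", "moderate", "good"),
    n_patients = c(20L, 126L, 180L, 123L),
    median_infarct_ml = c(271.0, 139.8, 55.9, 36.9),
    iqr_low_ml = c(105.8, 63.9, 27.4, 15.4),
    iqr_high_ml = c(411.8, 228.1, 107.8, 87.6),
    reference_model_mean_ml = c(280.5, 136.0, 51.7, 35.8)
  )
}

#' Calibrate collateral probability against target infarct volumes
#'
#' Maps each clinical collateral grade to a collateral-inclusion
#' probability by simulating a fully occluding thrombus over a probability
#' grid (several network seeds per grid point, collaterals resampled each
#' time), averaging the infarct volume, and picking for every grade the
#' grid probability whose mean infarct volume is closest to the target
#' median. The full response curve (mean and sd of infarct volume versus
#' probability) is returned alongside the per-grade assignment.
#'
#' @param targets named numeric vector of target infarct volumes (ml) per
#'   grade, decreasing with grade quality; defaults to the clinical
#'   medians of [collateral_grade_targets()].
#' @param probability_grid probabilities to simulate.
#' @param seeds network seeds to average over (collaterals are resampled
#'   for each).
#' @param config a [model_config()].
#' @param vessel occluded vessel (default the right-MCA branch).
#' @return A `collateral_calibration`: list with `grades` (tibble `grade`,
#'   `target_ml`, `probability`, `model_mean_ml`) and `curve` (tibble
#'   `probability`, `mean_infarct_ml`, `sd_infarct_ml`). A warning is
#'   issued when the mean response is not monotone over the grid.
#' @export
calibrate_collateral_probability <- function(
    targets = NULL,
    probability_grid = c(0.05, 0.25, 0.5, 0.65),
    seeds = 1:5,
    config = model_config(),
    vessel = "root_R-MCA") {
  if (is.null(targets)) {
    tt <- collateral_grade_targets()
    targets <- stats::setNames(tt$median_infarct_ml, tt$grade)
  }
  if (any(diff(unname(targets)) > 0)) {
    stop("calibrate_collateral_probability: target volumes must decrease with grade quality",
         call. = FALSE)
  }
  sw <- sweep_thrombus(
    thrombus_lengths_mm = 10, permeabilities_mm2 = 0,
    collateral_probabilities = probability_grid, seeds = seeds,
    config = config, vessel = vessel)
  if (any(!is.na(sw$error))) {
    warning("calibration grid points failed: ",
            paste(unique(stats::na.omit(sw$error)), collapse = "; "))
  }
  curve <- dplyr::summarise(
    dplyr::group_by(sw, .data$collateral_probability),
    mean_infarct_ml = mean(.data$infarct_ml, na.rm = TRUE),
    sd_infarct_ml = stats::sd(.data$infarct_ml, na.rm = TRUE),
    .groups = "drop")
  curve <- dplyr::rename(curve, probability = "collateral_probability")
  if (any(diff(curve$mean_infarct_ml[order(curve$probability)]) > 0)) {
    warning("infarct-volume response is not monotone over the probability grid; ",
            "inspect the attached curve (small grids and few seeds are noisy)")
  }
  grades <- tibble::tibble(
    grade = names(targets),
    target_ml = unname(targets),
    probability = vapply(unname(targets), function(t) {
      curve$probability[which.min(abs(curve$mean_infarct_ml - t))]
    }, numeric(1)),
    model_mean_ml = vapply(unname(targets), function(t) {
      curve$mean_infarct_ml[which.min(abs(curve$mean_infarct_ml - t))]
    }, numeric(1))
  )
  structure(list(grades = grades, curve = curve, sweep = sw),
            class = "collateral_calibration")
}

#' @export
print.collateral_calibration <- function(x, ...) {
  cat("<collateral_calibration>\n")
  print(x$grades)
  invisible(x)
}
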