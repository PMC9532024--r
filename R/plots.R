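#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot outlet perfusion of a flow solution
#'
#' Pial outlet flow against local perfusion pressure, coloured by
#' perfusion territory; the dashed line marks the autoregulation target
#' flow when the solution was autoregulated.
#'
#' @param object a `bf_result`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot bf_result
#' @export
autoplot.bf_result <- function(object, ...) {
  df <- object$outlets
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = pa_to_mmhg(.data$pial_pressure_Pa - object$config$solver$outlet_pressure_Pa),
    y = .data$flow_ml_s, colour = .data$territory)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "perfusion pressure over outlet [mmHg]",
                  y = "outlet flow [ml/s]", colour = "territory")
  ar <- object$diagnostics$autoregulation
  if (!is.null(ar)) {
    p <- p + ggplot2::geom_hline(yintercept = ar$target_flow_ml_s,
                                 linetype = "dashed")
  }
  p
}

#' Plot per-outlet fractional flow change of a stroke run
#'
#' @param object a `stroke_result` simulated with a baseline.
#' @param ... unused.
#' @return A ggplot: fractional flow change by territory with the
#'   perfusion threshold marked.
#' @method autoplot stroke_result
#' @export
autoplot.stroke_result <- function(object, ...) {
  if (is.null(object$outlet_changes)) {
    stop("stroke result has no baseline; rerun simulate_stroke() with baseline=",
         call. = FALSE)
  }
  ggplot2::ggplot(object$outlet_changes,
                  ggplot2::aes(x = .data$territory, y = .data$dQ)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = object$config$infarct$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "fractional flow change") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a flow response curve
#'
#' Flow through the thrombus versus total segment resistance on log-log
#' axes; the sigmoid between the healthy plateau and the occlusive tail is
#' the map inverted for patient estimates.
#'
#' @param object a `response_curve`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot response_curve
#' @export
autoplot.response_curve <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$R_T_Pa_s_ml, y = .data$Q_thrombus_ml_s)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "segment resistance [Pa s/ml]",
                  y = "flow through thrombus [ml/s]",
                  title = sprintf("collateral probability %.2f",
                                  object$collateral_probability))
}

#' Plot a permeability/length sweep
#'
#' Pressure drop and thrombus flow against permeability, one line per
#' thrombus length, from the long-form [sweep_thrombus()] table.
#'
#' @param sweep tibble from [sweep_thrombus()].
#' @return A ggplot (faceted: pressure drop and flow).
#' @export
plot_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(sweep, dp_mmHg = pa_to_mmhg(.data$dp_Pa)),
    cols = c("dp_mmHg", "Q_thrombus_ml_s"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kappa_mm2, y = .data$value,
                                     colour = factor(.data$L_mm),
                                     group = interaction(.data$L_mm, .data$seed))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "permeability [mm²]", colour = "length [mm]",
                  y = NULL)
}

#' Plot an infarct-volume calibration curve
#'
#' Mean infarct volume versus collateral probability with the calibration
#' targets as horizontal lines.
#'
#' @param object a `collateral_calibration`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot collateral_calibration
#' @export
autoplot.collateral_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$probability, y = .data$mean_infarct_ml)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_infarct_ml - .data$sd_infarct_ml,
      ymax = .data$mean_infarct_ml + .data$sd_infarct_ml)) +
    ggplot2::geom_hline(data = object$grades,
                        ggplot2::aes(yintercept = .data$target_ml),
                        linetype = "dashed") +
    ggplot2::labs(x = "collateral probability", y = "mean infarct volume [ml]")
}
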