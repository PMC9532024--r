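#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a flow solution
#'
#' @param x a `bf_result`.
#' @param what which table: `"outlets"` (default), `"segments"` or
#'   `"nodes"`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy bf_result
#' @export
tidy.bf_result <- function(x, what = c("outlets", "segments", "nodes"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' One-row summary of a flow solution
#'
#' @param x a `bf_result`.
#' @param ... unused.
#' @return One-row tibble with inlet flow and pressure, total pial outlet
#'   flow, outlet count, iteration counts and residuals.
#' @method glance bf_result
#' @export
glance.bf_result <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(
    inlet_flow_ml_s = d$inlet_flow_ml_s,
    inlet_pressure_Pa = d$inlet_pressure_Pa,
    total_outlet_flow_ml_s = sum(x$outlets$flow_ml_s),
    n_outlets = nrow(x$outlets),
    elastic_iterations = d$elastic_iterations,
    eps_P = d$eps_P,
    mass_residual = d$mass_residual,
    autoreg_iterations = if (is.null(d$autoregulation)) NA_integer_ else
      d$autoregulation$iterations,
    eps_R = if (is.null(d$autoregulation)) NA_real_ else
      d$autoregulation$eps_R
  )
}

#' Tidy a stroke simulation
#'
#' @param x a `stroke_result`.
#' @param what `"changes"` (per-outlet fractional flow change, default
#'   when a baseline was supplied) or any table of [tidy.bf_result()].
#' @param ... unused.
#' @return A tibble.
#' @method tidy stroke_result
#' @export
tidy.stroke_result <- function(x, what = NULL, ...) {
  if (is.null(what)) {
    if (!is.null(x$outlet_changes)) return(x$outlet_changes)
    what <- "outlets"
  }
  if (what == "changes") {
    if (is.null(x$outlet_changes)) {
      stop("no baseline was supplied to simulate_stroke(); outlet changes unavailable",
           call. = FALSE)
    }
    return(x$outlet_changes)
  }
  tidy.bf_result(x, what)
}

#' @method glance stroke_result
#' @export
glance.stroke_result <- function(x, ...) {
  base <- glance.bf_result(x)
  dplyr::bind_cols(base, tibble::tibble(
    R_T_Pa_s_ml = x$thrombus$R_T_Pa_s_ml,
    dp_mmHg = x$thrombus$dp_mmHg,
    Q_thrombus_ml_s = x$thrombus$Q_thrombus_ml_s,
    Q_collateral_ml_s = x$thrombus$Q_collateral_ml_s,
    Q_total_ml_s = x$thrombus$Q_total_ml_s,
    infarct_ml = if (is.null(x$infarct_ml)) NA_real_ else x$infarct_ml
  ))
}

#' @method tidy response_curve
#' @export
tidy.response_curve <- function(x, ...) x$table

#' @method glance response_curve
#' @export
glance.response_curve <- function(x, ...) {
  tibble::tibble(
    collateral_probability = x$collateral_probability,
    n_seeds = length(x$seeds),
    healthy_flow_ml_s = x$healthy_flow_ml_s,
    occlusive_dp_mmHg = pa_to_mmhg(x$occlusive$dp_Pa),
    occlusive_infarct_ml = x$occlusive$infarct_ml,
    R_vessel_Pa_s_ml = x$host$R_vessel_Pa_s_ml
  )
}

#' @method tidy collateral_calibration
#' @export
tidy.collateral_calibration <- function(x, ...) x$grades

#' @method glance collateral_calibration
#' @export
glance.collateral_calibration <- function(x, ...) {
  tibble::tibble(
    n_grid = nrow(x$curve),
    n_runs = nrow(x$sweep),
    monotone = !is.unsorted(rev(x$curve$mean_infarct_ml[order(x$curve$probability)]))
  )
}
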