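#' Autoregulation target flow per outlet
#'
#' Cerebral autoregulation aims each penetrating-artery outlet at an equal
#' share of total cerebral flow: `q = Q_brain / N_total`.
#'
#' @param config a [model_config()] (uses `autoregulation.Q_brain_ml_s`).
#' @param N_total number of pial outlets.
#' @return Target flow per outlet, ml/s.
#' @examples
#' target_outlet_flow(model_config(), 1000) # 0.0125
#' @export
target_outlet_flow <- function(config, N_total) {
  stopifnot(N_total > 0)
  config$autoregulation$Q_brain_ml_s / N_total
}

#' Autoregulated outlet resistance update with physiological clamps
#'
#' One autoregulation update: the outlet resistance that would deliver the
#' target flow under the current perfusion pressure,
#' `R = (P_i - P_out) / q`, clamped to the physiological range
#' `[P_low/q, P_upp/q]`. Hitting the lower clamp corresponds to maximal
#' vessel dilation, the upper clamp to maximal constriction.
#'
#' @param P_i pressure at the outlet's pial node, Pa (vectorised).
#' @param P_out venous outlet pressure, Pa.
#' @param q target flow per outlet, ml/s.
#' @param config a [model_config()] (uses `autoregulation.P_low_mmHg`,
#'   `autoregulation.P_upp_mmHg`).
#' @return Resistance(s), Pa s/ml.
#' @export
update_outlet_resistance <- function(P_i, P_out, q, config = model_config()) {
  stopifnot(q > 0)
  R_low <- mmhg_to_pa(config$autoregulation$P_low_mmHg) / q
  R_upp <- mmhg_to_pa(config$autoregulation$P_upp_mmHg) / q
  pmin(pmax((P_i - P_out) / q, R_low), R_upp)
}

#' Iterate outlet resistances to the autoregulation set-point
#'
#' Fixed-point loop: solve the full compliant-vessel system, then update
#' every pial outlet resistance synchronously from the solved pressure
#' field via the clamped autoregulation law, until the relative resistance
#' change (infinity norm) falls below `autoregulation.tol` (default 1e-6).
#' In a healthy network the converged state delivers the target flow
#' `Q_brain / N_total` at every unclamped outlet; downstream of an
#' occlusion, outlets in the perfusion-deficit region run into the
#' maximal-dilation clamp.
#'
#' An optional damping factor stabilises oscillatory cases; damping is
#' reduced automatically if the residual stops decreasing. The fixed point
#' itself is damping-independent.
#'
#' @param network a calibrated, discretized `vascular_network` (possibly
#'   with a thrombus applied via [apply_thrombus()]).
#' @param config a [model_config()].
#' @return A `bf_result` whose `outlets` tibble carries the converged
#'   flows, resistances and clamp status, and whose `network` element
#'   stores the updated resistances for reuse (e.g. warm-starting stroke
#'   runs from the healthy state).
#' @export
autoregulate <- function(network, config = network$meta$config) {
  if (is.null(network$segments)) network <- discretize_network(network)
  sol <- config$solver
  aut <- config$autoregulation
  sv <- prepare_solver(network, config)
  N_total <- nrow(network$outlets)
  q <- target_outlet_flow(config, N_total)
  R <- network$outlets$resistance_Pa_s_ml
  body_R <- network$meta$body_outlet_R
  if (any(is.na(R)) || is.null(body_R)) {
    stop("autoregulate requires a calibrated network (run calibrate_network() first)",
         call. = FALSE)
  }
  R_low <- mmhg_to_pa(aut$P_low_mmHg) / q
  R_upp <- mmhg_to_pa(aut$P_upp_mmHg) / q
  relax <- aut$relaxation
  radii <- network$state$radii_mm
  eps_hist <- numeric()
  st <- NULL
  converged <- FALSE
  for (it in seq_len(aut$max_iter)) {
    st <- elastic_fixed_point(sv, config, R, body_R, radii)
    radii <- st$r
    P_i <- st$P[sv$pial_rows]
    R_target <- pmin(pmax((P_i - sol$outlet_pressure_Pa) / q, R_low), R_upp)
    # per-outlet relative change; for an unclamped outlet this equals the
    # relative deviation of its current flow from the set-point q
    eps_R <- max(abs(R_target - R) / R)
    eps_hist <- c(eps_hist, eps_R)
    if (eps_R < aut$tol) {
      converged <- TRUE # break before updating: state is self-consistent
      break
    }
    R <- R + relax * (R_target - R)
    # fall back to damped updates if the residual stalls
    if (it >= 6L && relax > 0.45 &&
        all(diff(utils::tail(eps_hist, 4)) > 0)) {
      relax <- relax * 0.5
    }
  }
  if (!converged) {
    stop(sprintf("autoregulation did not converge: eps_R = %.3e after %d iterations (history: %s)",
                 utils::tail(eps_hist, 1), length(eps_hist),
                 paste(sprintf("%.1e", utils::tail(eps_hist, 5)), collapse = " ")),
         call. = FALSE)
  }
  network$outlets$resistance_Pa_s_ml <- R
  network$state <- list(radii_mm = radii)
  autoreg <- list(iterations = length(eps_hist),
                  eps_R = utils::tail(eps_hist, 1),
                  target_flow_ml_s = q,
                  R_low = R_low, R_upp = R_upp,
                  history = eps_hist)
  res <- build_result(network, sv, st, config, R, body_R, autoreg)
  res$outlets$clamped <- dplyr::case_when(
    abs(res$outlets$resistance_Pa_s_ml - R_low) < 1e-9 * R_low ~ "dilation_floor",
    abs(res$outlets$resistance_Pa_s_ml - R_upp) < 1e-9 * R_upp ~ "constriction_ceiling",
    TRUE ~ "none"
  )
  res
}
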