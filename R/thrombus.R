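#' Describe a permeable thrombus
#'
#' A thrombus occupies a contiguous span of a host vessel and is modelled
#' as a Darcy porous medium with an effective permeability. Specify either
#' `permeability_mm2` (with `length_mm`) or, for response-curve work, the
#' total segment resistance directly via `resistance_Pa_s_ml`.
#'
#' @param vessel host vessel: a vessel id or a vessel name (the default
#'   synthetic network names its first right-MCA branch `root_R-MCA`, the
#'   standard occlusion site).
#' @param length_mm thrombus length, mm (clinically 3 to 28 mm).
#' @param permeability_mm2 Darcy permeability, mm^2; 0 means fully
#'   occluding.
#' @param resistance_Pa_s_ml alternative to `length_mm` +
#'   `permeability_mm2`: prescribe the total resistance of the
#'   clot-bearing vessel directly.
#' @return An object of class `thrombus`.
#' @export
thrombus_spec <- function(vessel = "root_R-MCA", length_mm = NULL,
                          permeability_mm2 = NULL,
                          resistance_Pa_s_ml = NULL) {
  if (is.null(resistance_Pa_s_ml)) {
    if (is.null(length_mm) || is.null(permeability_mm2)) {
      stop("thrombus_spec: give either resistance_Pa_s_ml or both length_mm and permeability_mm2",
           call. = FALSE)
    }
    if (length_mm <= 0) stop("thrombus_spec: length_mm must be positive", call. = FALSE)
    if (permeability_mm2 < 0) stop("thrombus_spec: permeability_mm2 must be non-negative",
                                   call. = FALSE)
  }
  structure(list(vessel = vessel, length_mm = length_mm,
                 permeability_mm2 = permeability_mm2,
                 resistance_Pa_s_ml = resistance_Pa_s_ml),
            class = "thrombus")
}

#' Darcy resistance of a porous thrombus
#'
#' Darcy's law integrated over a one-dimensional vessel span gives
#' \eqn{Q = \frac{\kappa A}{\mu L} \Delta p}, i.e. a hydraulic resistance
#' \deqn{R_{thrombus} = \frac{\mu L}{\kappa A}.}
#' Zero permeability returns `Inf`, the fully-occluding sentinel (the
#' solver then removes the span's conductance entirely).
#'
#' @param kappa_mm2 permeability, mm^2.
#' @param A_mm2 cross-sectional (lumen) area, mm^2.
#' @param L_mm thrombus length, mm.
#' @param mu dynamic viscosity, Pa s.
#' @return Resistance, Pa s/ml. Vectorised.
#' @examples
#' darcy_resistance(1e-5, 4.5, 10) # ~7.78e5 Pa s/ml
#' @export
darcy_resistance <- function(kappa_mm2, A_mm2, L_mm, mu = 3.5e-3) {
  if (any(A_mm2 <= 0) || any(L_mm <= 0) || any(mu <= 0)) {
    stop("darcy_resistance: A, L and mu must be positive", call. = FALSE)
  }
  if (any(kappa_mm2 < 0)) {
    stop("darcy_resistance: permeability must be non-negative", call. = FALSE)
  }
  kappa_m2 <- kappa_mm2 * MM_TO_M^2
  A_m2 <- A_mm2 * MM_TO_M^2
  L_m <- L_mm * MM_TO_M
  R_SI <- ifelse(kappa_mm2 == 0, Inf, mu * L_m / (kappa_m2 * A_m2))
  R_SI / PASML_TO_PASM3
}

resolve_vessel <- function(network, vessel) {
  v <- network$vessels
  row <- if (is.character(vessel)) which(!is.na(v$name) & v$name == vessel)
         else which(v$id == vessel)
  if (length(row) != 1L) {
    stop("thrombus host vessel not found in network: ", vessel, call. = FALSE)
  }
  v[row, ]
}

#' Total resistance of the clot-bearing vessel
#'
#' Series sum of the Darcy thrombus resistance and the host vessel's own
#' hydraulic resistance: \eqn{R_T = R_{thrombus} + R_{vessel}}. The
#' Darcy cross-section is the host lumen area at reference radius,
#' \eqn{A = \pi r_0^2}. The vessel term is generally small; at low
#' permeability the thrombus term dominates. The clot-bearing vessel is
#' treated as a single hydraulic element of resistance `R_T`, which makes
#' the flow and pressure drop functions of `R_T` alone regardless of how
#' permeability and length combine to produce it.
#'
#' @param thrombus a [thrombus_spec()].
#' @param network a `vascular_network` containing the host vessel.
#' @param config a [model_config()].
#' @return Resistance, Pa s/ml (`Inf` for a fully occluding clot).
#' @export
thrombus_resistance <- function(thrombus, network,
                                config = network$meta$config) {
  host <- resolve_vessel(network, thrombus$vessel)
  if (!is.null(thrombus$resistance_Pa_s_ml)) return(thrombus$resistance_Pa_s_ml)
  if (thrombus$length_mm > host$length_mm) {
    stop(sprintf("thrombus (%.1f mm) is longer than its host vessel (%.1f mm)",
                 thrombus$length_mm, host$length_mm), call. = FALSE)
  }
  A <- pi * host$r0_mm^2
  R_thr <- darcy_resistance(thrombus$permeability_mm2, A, thrombus$length_mm,
                            config$solver$viscosity_Pa_s)
  R_ves <- vessel_resistance(host$r0_mm, host$length_mm,
                             config$solver$viscosity_Pa_s, config$solver$zeta)
  unname(R_thr + R_ves)
}

#' Insert a thrombus into a network
#'
#' Replaces the conductance of the clot-bearing vessel by `1/R_T`
#' (distributed over its discretized segments in proportion to length, so
#' the series total is exact) and freezes the span out of the elastic
#' radius updates: the clot is rigid. A fully occluding clot (zero
#' permeability) removes the conductance entirely rather than using a
#' large finite resistance.
#'
#' @param network a discretized `vascular_network`.
#' @param thrombus a [thrombus_spec()].
#' @return The network with the thrombus applied and recorded in
#'   `meta$thrombus`.
#' @export
apply_thrombus <- function(network, thrombus) {
  if (is.null(network$segments)) network <- discretize_network(network)
  host <- resolve_vessel(network, thrombus$vessel)
  R_T <- thrombus_resistance(thrombus, network)
  rows <- which(network$segments$vessel_id == host$id)
  frac <- network$segments$length_mm[rows] / sum(network$segments$length_mm[rows])
  if (!"G_fixed_SI" %in% names(network$segments)) {
    network$segments$G_fixed_SI <- NA_real_
  }
  if (is.infinite(R_T)) {
    # fully occluding: remove the proximal segment's conductance entirely;
    # the remaining (flowless) segments keep a rigid conductance so their
    # interior nodes stay hydraulically tied to the distal pressure
    network$segments$G_fixed_SI[rows] <- vessel_conductance(
      network$segments$r0_mm[rows], network$segments$length_mm[rows],
      network$meta$config$solver$viscosity_Pa_s,
      network$meta$config$solver$zeta)
    network$segments$G_fixed_SI[rows[1]] <- 0
  } else {
    network$segments$G_fixed_SI[rows] <- 1 / (R_T * frac * PASML_TO_PASM3)
  }
  network$meta$thrombus <- list(spec = thrombus, R_T_Pa_s_ml = R_T,
                                host_vessel = host$id,
                                host_from = host$from, host_to = host$to,
                                territory = host$territory,
                                segment_rows = rows)
  network
}

# Net collateral inflow (ml/s) into a territory from a solved state.
collateral_inflow <- function(result, territory) {
  net <- result$network
  segs <- result$segments
  coll <- net$vessels[net$vessels$is_collateral, ]
  if (nrow(coll) == 0L) return(0)
  terr_of <- stats::setNames(net$nodes$territory, net$nodes$id)
  a_in <- terr_of[as.character(coll$from)] == territory
  b_in <- terr_of[as.character(coll$to)] == territory
  sel <- xor(a_in, b_in)
  if (!any(sel)) return(0)
  inflow <- 0
  for (i in which(sel)) {
    srow <- which(segs$vessel_id == coll$id[i])[1]
    q <- segs$flow_ml_s[srow] # oriented vessel from -> to
    inflow <- inflow + if (b_in[i]) q else -q
  }
  inflow
}

#' Simulate an acute ischaemic stroke
#'
#' Applies a thrombus to a calibrated healthy network, re-runs
#' autoregulation, and summarises the occlusion haemodynamics: pressure
#' drop over the clot-bearing vessel, flow through the thrombus, net
#' collateral inflow into the affected territory, and (when a healthy
#' baseline is supplied) the per-outlet fractional flow change and infarct
#' volume.
#'
#' @param network a calibrated `vascular_network`, ideally carrying the
#'   healthy autoregulated state (output `network` of [autoregulate()])
#'   so the stroke run warm-starts from it.
#' @param thrombus a [thrombus_spec()].
#' @param config a [model_config()].
#' @param baseline optional healthy `bf_result` for infarct estimation.
#' @return A `stroke_result`: a `bf_result` with an extra `thrombus`
#'   summary and, if a baseline was given, `outlet_changes` and
#'   `infarct_ml`.
#' @export
simulate_stroke <- function(network, thrombus,
                            config = network$meta$config, baseline = NULL) {
  net_t <- apply_thrombus(network, thrombus)
  res <- autoregulate(net_t, config)
  th <- net_t$meta$thrombus
  node_idx <- match(c(th$host_from, th$host_to), res$nodes$id)
  dp <- res$nodes$pressure_Pa[node_idx[1]] - res$nodes$pressure_Pa[node_idx[2]]
  Q_thr <- res$segments$flow_ml_s[th$segment_rows[1]]
  Q_coll <- collateral_inflow(res, th$territory)
  res$thrombus <- list(
    spec = thrombus, R_T_Pa_s_ml = th$R_T_Pa_s_ml,
    territory = th$territory,
    dp_Pa = dp, dp_mmHg = pa_to_mmhg(dp),
    Q_thrombus_ml_s = Q_thr, Q_collateral_ml_s = Q_coll,
    Q_total_ml_s = Q_thr + Q_coll
  )
  if (!is.null(baseline)) {
    res$outlet_changes <- classify_outlets(baseline, res, config)
    res$infarct_ml <- infarct_volume(res$outlet_changes, config,
                                     V_brain_ml = network$meta$brain_volume_ml)
  }
  class(res) <- c("stroke_result", class(res))
  res
}

#' @export
print.stroke_result <- function(x, ...) {
  NextMethod()
  t <- x$thrombus
  cat(sprintf("  thrombus: R_T = %.4g Pa s/ml, dp = %.4g mmHg\n",
              t$R_T_Pa_s_ml, t$dp_mmHg))
  cat(sprintf("  flows to %s: thrombus %.4g + collateral %.4g = %.4g ml/s\n",
              t$territory, t$Q_thrombus_ml_s, t$Q_collateral_ml_s,
              t$Q_total_ml_s))
  if (!is.null(x$infarct_ml)) cat(sprintf("  infarct volume: %.1f ml\n", x$infarct_ml))
  invisible(x)
}

#' Sweep thrombus permeability, length and collateral score
#'
#' Runs one full stroke simulation per grid point over thrombus lengths,
#' permeabilities, collateral probabilities and network seeds. For each
#' (seed, probability) a fresh network is generated, calibrated and
#' autoregulated to its healthy baseline; each (length, permeability) then
#' yields pressure drop, thrombus flow, collateral flow, total flow to the
#' affected territory and infarct volume. Solver failures are recorded per
#' grid point and the sweep continues.
#'
#' @param thrombus_lengths_mm,permeabilities_mm2 numeric grids.
#' @param collateral_probabilities,seeds grids over network realizations.
#' @param config a [model_config()] (its own probability/seed entries are
#'   overridden by the grids).
#' @param vessel host vessel name or id.
#' @param out_dir optional directory: each grid point is written to its
#'   own CSV as it completes and already-present grid points are skipped,
#'   so an interrupted sweep resumes where it stopped.
#' @return Long-form tibble with one row per grid point: `seed`,
#'   `collateral_probability`, `L_mm`, `kappa_mm2`, `R_T_Pa_s_ml`,
#'   `dp_Pa`, `Q_thrombus_ml_s`, `Q_collateral_ml_s`, `Q_total_ml_s`,
#'   `infarct_ml`, `error`.
#' @export
sweep_thrombus <- function(thrombus_lengths_mm, permeabilities_mm2,
                           collateral_probabilities, seeds,
                           config = model_config(), vessel = "root_R-MCA",
                           out_dir = NULL) {
  stopifnot(length(thrombus_lengths_mm) > 0, length(permeabilities_mm2) > 0,
            length(collateral_probabilities) > 0, length(seeds) > 0)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- tidyr::expand_grid(
    seed = as.integer(seeds),
    collateral_probability = collateral_probabilities,
    L_mm = thrombus_lengths_mm,
    kappa_mm2 = permeabilities_mm2
  )
  rows <- vector("list", nrow(grid))
  baseline_key <- ""
  healthy <- NULL; net <- NULL
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    point_file <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("grid_%04d.csv", i))
    } else NULL
    if (!is.null(point_file) && file.exists(point_file)) {
      rows[[i]] <- readr::read_csv(point_file, show_col_types = FALSE)
      next
    }
    key <- paste(g$seed, g$collateral_probability)
    row <- tryCatch({
      if (key != baseline_key) {
        cfg_i <- model_config(
          network = utils::modifyList(config$network,
            list(collateral_probability = g$collateral_probability,
                 seed = g$seed)),
          solver = config$solver, autoregulation = config$autoregulation,
          infarct = config$infarct, inversion = config$inversion)
        net_i <- discretize_network(generate_network(cfg_i))
        net_i <- calibrate_network(net_i, cfg_i)
        healthy <- autoregulate(net_i, cfg_i)
        net <- healthy$network
        baseline_key <- key
      }
      th <- thrombus_spec(vessel, length_mm = g$L_mm,
                          permeability_mm2 = g$kappa_mm2)
      stroke <- simulate_stroke(net, th, net$meta$config, baseline = healthy)
      tibble::tibble(
        g,
        R_T_Pa_s_ml = stroke$thrombus$R_T_Pa_s_ml,
        dp_Pa = stroke$thrombus$dp_Pa,
        Q_thrombus_ml_s = stroke$thrombus$Q_thrombus_ml_s,
        Q_collateral_ml_s = stroke$thrombus$Q_collateral_ml_s,
        Q_total_ml_s = stroke$thrombus$Q_total_ml_s,
        infarct_ml = stroke$infarct_ml,
        error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(g, R_T_Pa_s_ml = NA_real_, dp_Pa = NA_real_,
                     Q_thrombus_ml_s = NA_real_, Q_collateral_ml_s = NA_real_,
                     Q_total_ml_s = NA_real_, infarct_ml = NA_real_,
                     error = conditionMessage(e))
    })
    rows[[i]] <- row
    if (!is.null(point_file)) readr::write_csv(row, point_file)
  }
  dplyr::bind_rows(rows)
}
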