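#' Flow through an occlusion from dynamic-CTA measurements
#'
#' Contrast-based estimate of the residual flow through an occluded
#' segment: \eqn{Q = \epsilon A_{MCA} L / \Delta t}, where the void
#' fraction \eqn{\epsilon} is the ratio of mean contrast intensity inside
#' the thrombus to the contralateral unoccluded vessel, `A_MCA` the
#' contralateral lumen area, `L` the thrombus length and \eqn{\Delta t}
#' the contrast transit time over the occlusion. A zero void fraction is a
#' valid measurement (fully impervious clot, zero flow).
#'
#' @param measurements tibble/data frame with columns `transit_time_s`,
#'   `void_fraction`, `length_mm`, `lumen_area_mm2` (and any id columns,
#'   preserved).
#' @return The input tibble with a `flow_ml_s` column appended.
#' @examples
#' m <- tibble::tibble(transit_time_s = 5, void_fraction = 0.2,
#'                     length_mm = 10, lumen_area_mm2 = 4.5)
#' flow_from_measurement(m)$flow_ml_s # 1.8e-3
#' @export
flow_from_measurement <- function(measurements) {
  m <- tibble::as_tibble(measurements)
  required <- c("transit_time_s", "void_fraction", "length_mm", "lumen_area_mm2")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0L) {
    stop("flow_from_measurement: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(m$transit_time_s <= 0) || any(m$length_mm <= 0) ||
      any(m$lumen_area_mm2 <= 0)) {
    stop("flow_from_measurement: transit time, length and lumen area must be positive",
         call. = FALSE)
  }
  if (any(m$void_fraction < 0) || any(m$void_fraction > 1)) {
    stop("flow_from_measurement: void fraction must lie in [0, 1]", call. = FALSE)
  }
  # epsilon * A[mm^2] * L[mm] / dt[s] = mm^3/s; 1 ml = 1000 mm^3
  m$flow_ml_s <- m$void_fraction * m$lumen_area_mm2 * m$length_mm /
    m$transit_time_s / 1000
  m
}

#' Simulated flow response curve of the occluded vessel
#'
#' Tabulates the mean flow through the thrombus (plus pressure drop and
#' infarct volume) as a function of the total segment resistance `R_T`,
#' for one collateral score, averaged over several network seeds
#' (collaterals resampled each time). The tabulation is strictly monotone
#' in `R_T` and is the forward map inverted by [invert_to_resistance()].
#' A fully occluding run is included as the infinite-resistance limit.
#'
#' @param collateral_probability collateral score of the curve.
#' @param resistance_grid_Pa_s_ml sorted grid spanning several decades
#'   (default `inversion.resistance_grid_Pa_s_ml`, 1e2 to 1e9).
#' @param seeds network seeds averaged over (default
#'   `1:inversion.n_seeds`).
#' @param config a [model_config()].
#' @param vessel occluded vessel name or id.
#' @return A `response_curve`: list with `table` (tibble `R_T_Pa_s_ml`,
#'   `Q_thrombus_ml_s`, `dp_Pa`, `infarct_ml`, `sd_Q`), `occlusive`
#'   (fully-occluding reference: `dp_Pa`, `infarct_ml`), `healthy_flow_ml_s`,
#'   `host` geometry (length, radius, lumen area, vessel resistance) and
#'   the generating settings.
#' @export
build_response_curve <- function(collateral_probability,
                                 resistance_grid_Pa_s_ml = NULL,
                                 seeds = NULL,
                                 config = model_config(),
                                 vessel = "root_R-MCA") {
  inv <- config$inversion
  if (is.null(resistance_grid_Pa_s_ml)) {
    resistance_grid_Pa_s_ml <- inv$resistance_grid_Pa_s_ml
  }
  if (is.null(seeds)) seeds <- seq_len(inv$n_seeds)
  grid <- sort(resistance_grid_Pa_s_ml)
  if (log10(max(grid) / min(grid)) < 4) {
    stop("build_response_curve: resistance grid must span at least 4 decades",
         call. = FALSE)
  }
  per_seed <- vector("list", length(seeds))
  host <- NULL; healthy_flow <- numeric(length(seeds))
  occl <- matrix(NA_real_, length(seeds), 2,
                 dimnames = list(NULL, c("dp_Pa", "infarct_ml")))
  for (si in seq_along(seeds)) {
    cfg_i <- model_config(
      network = utils::modifyList(config$network,
        list(collateral_probability = collateral_probability,
             seed = as.integer(seeds[si]))),
      solver = config$solver, autoregulation = config$autoregulation,
      infarct = config$infarct, inversion = config$inversion)
    net <- discretize_network(generate_network(cfg_i))
    net <- calibrate_network(net, cfg_i)
    healthy <- autoregulate(net, cfg_i)
    net <- healthy$network
    if (is.null(host)) {
      hv <- resolve_vessel(net, vessel)
      host <- list(
        vessel = vessel, length_mm = hv$length_mm, r0_mm = hv$r0_mm,
        lumen_area_mm2 = pi * hv$r0_mm^2,
        R_vessel_Pa_s_ml = vessel_resistance(hv$r0_mm, hv$length_mm,
                                             config$solver$viscosity_Pa_s,
                                             config$solver$zeta))
    }
    healthy_flow[si] <- healthy$segments$flow_ml_s[
      which(healthy$segments$vessel_id == resolve_vessel(net, vessel)$id)[1]]
    rows <- lapply(grid, function(R) {
      th <- thrombus_spec(vessel, resistance_Pa_s_ml = R)
      s <- simulate_stroke(net, th, cfg_i, baseline = healthy)
      tibble::tibble(R_T_Pa_s_ml = R, Q_thrombus_ml_s = s$thrombus$Q_thrombus_ml_s,
                     dp_Pa = s$thrombus$dp_Pa, infarct_ml = s$infarct_ml)
    })
    per_seed[[si]] <- dplyr::bind_rows(rows)
    s_occ <- simulate_stroke(net, thrombus_spec(vessel, length_mm = 10,
                                                permeability_mm2 = 0),
                             cfg_i, baseline = healthy)
    occl[si, ] <- c(s_occ$thrombus$dp_Pa, s_occ$infarct_ml)
  }
  all <- dplyr::bind_rows(per_seed, .id = "seed_idx")
  tab <- dplyr::summarise(
    dplyr::group_by(all, .data$R_T_Pa_s_ml),
    sd_Q = stats::sd(.data$Q_thrombus_ml_s),
    Q_thrombus_ml_s = mean(.data$Q_thrombus_ml_s),
    dp_Pa = mean(.data$dp_Pa),
    infarct_ml = mean(.data$infarct_ml),
    .groups = "drop")
  tab <- tab[order(tab$R_T_Pa_s_ml), ]
  dq <- diff(tab$Q_thrombus_ml_s)
  if (any(dq > 1e-6 * max(tab$Q_thrombus_ml_s))) {
    stop("build_response_curve: mean flow is not monotone decreasing in resistance ",
         "beyond noise tolerance; widen the grid or add seeds", call. = FALSE)
  }
  # flatten sub-noise wiggles so the interpolant is strictly invertible
  tab$Q_thrombus_ml_s <- rev(cummax(rev(tab$Q_thrombus_ml_s)))
  structure(list(
    table = tab,
    occlusive = list(dp_Pa = mean(occl[, "dp_Pa"]),
                     infarct_ml = mean(occl[, "infarct_ml"])),
    healthy_flow_ml_s = mean(healthy_flow),
    host = host,
    collateral_probability = collateral_probability,
    seeds = seeds
  ), class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat("<response_curve> collateral probability", x$collateral_probability,
      "over", length(x$seeds), "seed(s)\n")
  cat(sprintf("  healthy vessel flow: %.4g ml/s; R_vessel = %.4g Pa s/ml\n",
              x$healthy_flow_ml_s, x$host$R_vessel_Pa_s_ml))
  print(x$table)
  invisible(x)
}

#' Invert a measured flow to a segment resistance
#'
#' Monotone inversion of the simulated flow response curve: the resistance
#' whose simulated flow through the thrombus equals the measured flow.
#' Interpolation is linear in log-log coordinates between tabulated knots.
#' Measured flows above the curve's healthy branch are an error; flows
#' below the lowest tabulated value are clamped to the largest grid
#' resistance with a warning; zero flow maps to infinite resistance.
#'
#' @param Q_measured measured flow(s), ml/s.
#' @param curve a [build_response_curve()] object.
#' @return Resistance(s), Pa s/ml (`Inf` for zero flow).
#' @export
invert_to_resistance <- function(Q_measured, curve) {
  tab <- curve$table
  lq <- log10(tab$Q_thrombus_ml_s)
  lr <- log10(tab$R_T_Pa_s_ml)
  vapply(Q_measured, function(q) {
    if (q < 0) stop("invert_to_resistance: negative flow", call. = FALSE)
    if (q == 0) return(Inf)
    if (q > max(tab$Q_thrombus_ml_s) * (1 + 1e-9)) {
      stop(sprintf("measured flow %.4g ml/s exceeds the curve's healthy branch (%.4g ml/s)",
                   q, max(tab$Q_thrombus_ml_s)), call. = FALSE)
    }
    if (q < min(tab$Q_thrombus_ml_s)) {
      warning("measured flow below tabulated range; clamped to the largest grid resistance")
      return(max(tab$R_T_Pa_s_ml))
    }
    # lq is increasing when sorted by decreasing R
    10^stats::approx(rev(lq), rev(lr), xout = log10(q), ties = "ordered")$y
  }, numeric(1))
}

#' Effective permeability from a segment resistance
#'
#' Exact algebraic inverse of the Darcy series model:
#' \eqn{\kappa = \mu L / (A (R_T - R_{vessel}))}. A resistance at or
#' below the bare-vessel resistance means the clot adds nothing
#' measurable; the infinite-permeability sentinel is returned with a
#' warning.
#'
#' @param R_T_Pa_s_ml total segment resistance, Pa s/ml.
#' @param L_mm thrombus length, mm.
#' @param A_mm2 lumen area, mm^2.
#' @param mu viscosity, Pa s.
#' @param R_vessel_Pa_s_ml host vessel resistance, Pa s/ml (default 0).
#' @return Permeability, mm^2. Vectorised over `R_T_Pa_s_ml`.
#' @export
permeability_from_resistance <- function(R_T_Pa_s_ml, L_mm, A_mm2,
                                         mu = 3.5e-3, R_vessel_Pa_s_ml = 0) {
  dR <- R_T_Pa_s_ml - R_vessel_Pa_s_ml
  if (any(dR <= 0 & is.finite(R_T_Pa_s_ml))) {
    warning("resistance at or below the bare-vessel resistance; infinite permeability")
  }
  kappa_m2 <- mu * (L_mm * MM_TO_M) /
    ((A_mm2 * MM_TO_M^2) * (dR * PASML_TO_PASM3))
  out <- kappa_m2 / MM_TO_M^2
  out[dR <= 0] <- Inf
  out[is.infinite(R_T_Pa_s_ml)] <- 0
  out
}

#' Estimate thrombus properties for measured patients
#'
#' Chains the full inversion pipeline per patient: measured transit time,
#' void fraction, thrombus length and lumen area give the flow through the
#' occlusion; the flow is inverted on the simulated response curve of the
#' patient's collateral grade to a segment resistance; the resistance
#' yields the effective Darcy permeability, and the pressure drop and
#' infarct volume are read from the simulation at the inverted
#' resistance. Fully impervious measurements (zero void fraction) receive
#' the fully-occluding simulation's pressure drop and infarct volume.
#' Measured flows exceeding the healthy branch are clamped to it with a
#' per-patient warning.
#'
#' @param measurements tibble with the measurement columns of
#'   [flow_from_measurement()].
#' @param curve the [build_response_curve()] for the cohort's collateral
#'   grade.
#' @param config a [model_config()].
#' @return The measurements tibble with appended columns `flow_ml_s`,
#'   `R_T_Pa_s_ml`, `dp_mmHg`, `kappa_mm2`, `infarct_ml`, `clamped`.
#' @export
estimate_patients <- function(measurements, curve, config = model_config()) {
  m <- flow_from_measurement(measurements)
  healthy_Q <- max(curve$table$Q_thrombus_ml_s)
  m$clamped <- m$flow_ml_s > healthy_Q
  if (any(m$clamped)) {
    warning(sum(m$clamped),
            " patient(s) with measured flow above the healthy branch; clamped")
  }
  q <- pmin(m$flow_ml_s, healthy_Q)
  m$R_T_Pa_s_ml <- invert_to_resistance(q, curve)
  tab <- curve$table
  lr <- log10(tab$R_T_Pa_s_ml)
  interp_at <- function(y, R) {
    out <- stats::approx(lr, y, xout = log10(pmin(pmax(R, min(tab$R_T_Pa_s_ml)),
                                                  max(tab$R_T_Pa_s_ml))),
                         ties = "ordered")$y
    out[is.infinite(R)] <- NA_real_
    out
  }
  m$dp_mmHg <- pa_to_mmhg(interp_at(tab$dp_Pa, m$R_T_Pa_s_ml))
  m$infarct_ml <- interp_at(tab$infarct_ml, m$R_T_Pa_s_ml)
  occl <- is.infinite(m$R_T_Pa_s_ml)
  m$dp_mmHg[occl] <- pa_to_mmhg(curve$occlusive$dp_Pa)
  m$infarct_ml[occl] <- curve$occlusive$infarct_ml
  m$kappa_mm2 <- permeability_from_resistance(
    m$R_T_Pa_s_ml, m$length_mm, curve$host$lumen_area_mm2,
    config$solver$viscosity_Pa_s, curve$host$R_vessel_Pa_s_ml)
  m
}

#' Generate a synthetic patient-measurement cohort
#'
#' Stand-in for a clinical dynamic-CTA measurement table: samples transit
#' time (log-uniform, 1-30 s), void fraction (uniform, 0-0.5), thrombus
#' length (uniform, 3-28 mm, the clinically observed range) and
#' contralateral lumen area (uniform, 3-8 mm^2), reproducibly under a
#' seed. A cohort of 44 mirrors the size of the measurement study the
#' model is designed around.
#'
#' @param n number of patients.
#' @param ranges named list overriding any of `transit_time_s`,
#'   `void_fraction`, `length_mm`, `lumen_area_mm2` (each a length-2
#'   range).
#' @param seed integer RNG seed.
#' @return Tibble with `patient_id` and the four measurement columns.
#' @export
generate_synthetic_cohort <- function(n = 44, ranges = list(), seed = 1L) {
  stopifnot(n > 0)
  defaults <- list(transit_time_s = c(1, 30), void_fraction = c(0, 0.5),
                   length_mm = c(3, 28), lumen_area_mm2 = c(3, 8))
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown) > 0L) {
    stop("generate_synthetic_cohort: unknown range name(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  r <- utils::modifyList(defaults, ranges)
  if (any(vapply(r[c("transit_time_s", "length_mm", "lumen_area_mm2")],
                 function(x) any(x <= 0), logical(1)))) {
    stop("generate_synthetic_cohort: ranges must be positive", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      transit_time_s = exp(stats::runif(n, log(r$transit_time_s[1]),
                                        log(r$transit_time_s[2]))),
      void_fraction = stats::runif(n, r$void_fraction[1], r$void_fraction[2]),
      length_mm = stats::runif(n, r$length_mm[1], r$length_mm[2]),
      lumen_area_mm2 = stats::runif(n, r$lumen_area_mm2[1], r$lumen_area_mm2[2])
    )
  })
}
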