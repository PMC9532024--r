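#' Default model configuration
#'
#' Bundles every tunable parameter of the blood-flow model into one nested
#' list with the physiological defaults: inlet pressure 12 500 Pa, outlet
#' pressure 666 Pa, inlet flow 100 ml/s, blood viscosity 3.5 mPa s (the
#' standard large-vessel value), velocity-profile constant zeta = 9 (blunt
#' profile; 2 would be parabolic/Poiseuille), Poisson ratio 0.5, Young's
#' modulus 1.6 MPa for cerebral vessels, pial vessel radius 0.2 mm,
#' length-radius ratio 10, Murray exponent 3, brain volume 1390 ml,
#' cerebral flow 12.5 ml/s, autoregulation pressure limits 10-100 mmHg and
#' a perfusion threshold of 0.4 (infarcted when flow drops by 40% or more).
#'
#' The reference pressure of the pressure-area law defaults to diastolic
#' pressure, taken as 80 mmHg.
#'
#' @param ... named overrides. Either nested lists (`solver = list(zeta = 2)`)
#'   or dotted keys (`"solver.zeta" = 2`). Unknown keys are an error so that
#'   typos never pass silently.
#' @return A named nested list of class `collatflow_config` with components
#'   `network`, `solver`, `autoregulation`, `infarct`, `inversion`.
#' @examples
#' cfg <- model_config("solver.zeta" = 2)
#' cfg$solver$zeta
#' @export
model_config <- function(...) {
  defaults <- list(
    network = list(
      surface_resolution = 3L,
      sphere_radius_mm = 50,
      collateral_probability = 0.25,
      length_radius_ratio = 10,
      murray_exponent = 3,
      pial_radius_mm = 0.2,
      terminal_radius_mm = 0.25,
      brain_volume_ml = 1390,
      systemic_table = NA, # path to a user CSV; NA = packaged surrogate table
      seed = 1L
    ),
    solver = list(
      viscosity_Pa_s = 3.5e-3,
      zeta = 9,
      poisson = 0.5,
      reference_pressure_Pa = 80 * MMHG_TO_PA,
      inlet_pressure_Pa = 12500,
      outlet_pressure_Pa = 666,
      inlet_flow_ml_s = 100,
      young_modulus_Pa = 1.6e6,
      max_dx_mm = 2.5,
      min_nodes = 3L,
      pressure_tol = 1e-6,
      bc_tol = 1e-6,
      max_iterations = 500L,
      relaxation = 0.7,
      norm = "inf"
    ),
    autoregulation = list(
      Q_brain_ml_s = 12.5,
      P_low_mmHg = 10,
      P_upp_mmHg = 100,
      tol = 1e-6,
      max_iter = 200L,
      relaxation = 1
    ),
    infarct = list(
      threshold = 0.4
    ),
    inversion = list(
      n_seeds = 5L,
      resistance_grid_Pa_s_ml = 10^seq(2, 9, length.out = 15)
    )
  )
  cfg <- merge_config(defaults, flatten_overrides(list(...)))
  validate_config(cfg)
  structure(cfg, class = c("collatflow_config", "list"))
}

# turn c("solver.zeta" = 2) style overrides into nested lists
flatten_overrides <- function(overrides) {
  if (length(overrides) == 0L) return(list())
  out <- list()
  for (nm in names(overrides)) {
    if (nm == "") stop("all configuration overrides must be named", call. = FALSE)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    node <- overrides[[nm]]
    for (p in rev(parts)) node <- stats::setNames(list(node), p)
    out <- utils::modifyList(out, node)
  }
  out
}

merge_config <- function(defaults, overrides, path = character()) {
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L) {
    full <- paste(c(path, unknown[1]), collapse = ".")
    stop("unknown configuration key: ", full, call. = FALSE)
  }
  for (nm in names(overrides)) {
    if (is.null(overrides[[nm]])) next # NULL means "keep the default"
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]], c(path, nm))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  problems <- character()
  need <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  net <- cfg$network; sol <- cfg$solver; aut <- cfg$autoregulation
  need(net$surface_resolution >= 1, "network.surface_resolution must be >= 1")
  need(net$collateral_probability >= 0 && net$collateral_probability <= 1,
       "network.collateral_probability must lie in [0, 1]")
  need(net$murray_exponent > 0, "network.murray_exponent must be positive")
  need(net$pial_radius_mm > 0, "network.pial_radius_mm must be positive")
  need(net$length_radius_ratio > 0, "network.length_radius_ratio must be positive")
  need(net$brain_volume_ml > 0, "network.brain_volume_ml must be positive")
  need(sol$viscosity_Pa_s > 0, "solver.viscosity_Pa_s must be positive")
  need(sol$zeta >= 0, "solver.zeta must be non-negative")
  need(sol$poisson >= 0 && sol$poisson < 1, "solver.poisson must lie in [0, 1)")
  need(sol$inlet_pressure_Pa > sol$outlet_pressure_Pa,
       "solver.inlet_pressure_Pa must exceed solver.outlet_pressure_Pa")
  need(sol$pressure_tol > 0, "solver.pressure_tol must be positive")
  need(sol$bc_tol > 0, "solver.bc_tol must be positive")
  need(sol$relaxation > 0 && sol$relaxation <= 1,
       "solver.relaxation must lie in (0, 1]")
  need(sol$max_dx_mm > 0, "solver.max_dx_mm must be positive")
  need(sol$min_nodes >= 2, "solver.min_nodes must be >= 2")
  need(aut$P_low_mmHg < aut$P_upp_mmHg,
       "autoregulation.P_low_mmHg must be below autoregulation.P_upp_mmHg")
  need(aut$Q_brain_ml_s > 0, "autoregulation.Q_brain_ml_s must be positive")
  need(aut$tol > 0, "autoregulation.tol must be positive")
  need(cfg$infarct$threshold > 0 && cfg$infarct$threshold < 1,
       "infarct.threshold must lie in (0, 1)")
  if (length(problems) > 0L) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Read or write a model configuration as YAML
#'
#' `load_config()` reads a YAML file (possibly empty, possibly using dotted
#' keys) and merges it over the full default set; every violated invariant
#' is reported at once and unknown keys are an error. `save_config()` writes
#' the nested list back so that `load_config(save_config(cfg, f))` is the
#' identity.
#'
#' @param path file path.
#' @param config a `collatflow_config`.
#' @return `load_config()` a validated `collatflow_config`; `save_config()`
#'   the path, invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(model_config, raw)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "collatflow_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}
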