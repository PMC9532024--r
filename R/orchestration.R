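#' Run a reproducible experiment pipeline
#'
#' Executes the standard experiment stages — network generation, boundary
#' calibration, healthy autoregulated baseline, and optionally a stroke
#' run, a permeability/length sweep and a cohort inversion — writing every
#' stage's outputs as CSV into `out_dir` and recording a manifest
#' (configuration snapshot, seeds, package version, per-stage convergence
#' diagnostics, output inventory with MD5 checksums) sufficient to
#' reproduce the run. All randomness derives from `config$network$seed`.
#' A failing stage halts the pipeline with the partial manifest preserved
#' on disk.
#'
#' @param config a [model_config()].
#' @param stages subset of `c("generate", "calibrate", "healthy",
#'   "stroke", "sweep", "invert")`, executed in this order (prerequisites
#'   are implied: e.g. "healthy" forces "generate" and "calibrate").
#' @param out_dir output directory.
#' @param thrombus a [thrombus_spec()] for the "stroke" stage.
#' @param sweep_grid list with elements `lengths_mm`, `kappas_mm2`,
#'   `probabilities`, `seeds` for the "sweep" stage.
#' @param measurements measurement tibble (or CSV path) for "invert".
#' @param grade_probability collateral probability used for the inversion
#'   response curve.
#' @return The manifest, invisibly.
#' @export
run_experiment <- function(config = model_config(),
                           stages = c("generate", "calibrate", "healthy"),
                           out_dir,
                           thrombus = thrombus_spec(length_mm = 10,
                                                    permeability_mm2 = 0),
                           sweep_grid = NULL,
                           measurements = NULL,
                           grade_probability = config$network$collateral_probability) {
  valid <- c("generate", "calibrate", "healthy", "stroke", "sweep", "invert")
  stages <- match.arg(stages, valid, several.ok = TRUE)
  # imply prerequisites
  if (any(c("stroke", "invert") %in% stages)) stages <- union(stages, "healthy")
  if ("healthy" %in% stages) stages <- union(stages, "calibrate")
  if ("calibrate" %in% stages) stages <- union(stages, "generate")
  stages <- valid[valid %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("collatflow")),
    config = unclass(config),
    seed = config$network$seed,
    stages = list(),
    files = list()
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  flush_manifest <- function() {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  }
  record_files <- function(paths) {
    for (p in paths) {
      manifest$files[[basename(p)]] <<- unname(tools::md5sum(p))
    }
  }
  net <- NULL; healthy <- NULL
  for (stage in stages) {
    ok <- tryCatch({
      if (stage == "generate") {
        net <- discretize_network(generate_network(config))
        write_network(net, file.path(out_dir, "network"))
        record_files(file.path(out_dir, "network",
                               c("nodes.csv", "vessels.csv", "meta.json")))
        manifest$stages$generate <- list(
          n_nodes = nrow(net$nodes), n_vessels = nrow(net$vessels),
          N_total = net$meta$N_total)
      } else if (stage == "calibrate") {
        net <- calibrate_network(net, config)
        manifest$stages$calibrate <- net$meta$calibration[c("iterations", "mismatch")]
      } else if (stage == "healthy") {
        healthy <- autoregulate(net, config)
        net <- healthy$network
        write_result_csvs(healthy, out_dir, "healthy")
        record_files(file.path(out_dir, paste0("healthy_",
          c("nodes", "segments", "outlets"), ".csv")))
        manifest$stages$healthy <- unclass(glance.bf_result(healthy))
      } else if (stage == "stroke") {
        stroke <- simulate_stroke(net, thrombus, config, baseline = healthy)
        write_result_csvs(stroke, out_dir, "stroke")
        readr::write_csv(stroke$outlet_changes,
                         file.path(out_dir, "stroke_outlet_changes.csv"))
        jsonlite::write_json(
          list(infarct_ml = stroke$infarct_ml,
               N_outlets = sum(stroke$outlet_changes$infarcted),
               N_total = nrow(stroke$outlet_changes),
               threshold = config$infarct$threshold,
               thrombus = stroke$thrombus[c("R_T_Pa_s_ml", "dp_Pa",
                                            "Q_thrombus_ml_s",
                                            "Q_collateral_ml_s",
                                            "Q_total_ml_s")]),
          file.path(out_dir, "stroke_summary.json"),
          auto_unbox = TRUE, digits = NA)
        record_files(file.path(out_dir, c(
          paste0("stroke_", c("nodes", "segments", "outlets"), ".csv"),
          "stroke_outlet_changes.csv", "stroke_summary.json")))
        manifest$stages$stroke <- unclass(glance.stroke_result(stroke))
      } else if (stage == "sweep") {
        if (is.null(sweep_grid)) stop("sweep stage requires sweep_grid")
        sw <- sweep_thrombus(sweep_grid$lengths_mm, sweep_grid$kappas_mm2,
                             sweep_grid$probabilities, sweep_grid$seeds,
                             config = config,
                             out_dir = file.path(out_dir, "sweep_points"))
        readr::write_csv(sw, file.path(out_dir, "sweep.csv"))
        record_files(file.path(out_dir, "sweep.csv"))
        manifest$stages$sweep <- list(n_points = nrow(sw),
                                       n_failed = sum(!is.na(sw$error)))
      } else if (stage == "invert") {
        if (is.null(measurements)) stop("invert stage requires measurements")
        if (is.character(measurements)) {
          measurements <- readr::read_csv(measurements, show_col_types = FALSE)
        }
        curve <- build_response_curve(grade_probability, config = config)
        est <- estimate_patients(measurements, curve, config)
        readr::write_csv(est, file.path(out_dir, "estimates.csv"))
        readr::write_csv(curve$table, file.path(out_dir, "response_curve.csv"))
        qs <- function(x) stats::quantile(x[is.finite(x)],
                                          c(0.25, 0.5, 0.75), names = FALSE)
        jsonlite::write_json(
          list(R_T_Pa_s_ml = qs(est$R_T_Pa_s_ml), dp_mmHg = qs(est$dp_mmHg),
               kappa_mm2 = qs(est$kappa_mm2), infarct_ml = qs(est$infarct_ml)),
          file.path(out_dir, "estimate_quantiles.json"), digits = NA)
        record_files(file.path(out_dir, c("estimates.csv", "response_curve.csv",
                                          "estimate_quantiles.json")))
        manifest$stages$invert <- list(n_patients = nrow(est),
                                        n_clamped = sum(est$clamped))
      }
      TRUE
    }, error = function(e) {
      manifest$stages[[stage]] <<- list(error = conditionMessage(e))
      flush_manifest()
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    flush_manifest()
  }
  invisible(manifest)
}

write_result_csvs <- function(result, out_dir, prefix) {
  readr::write_csv(result$nodes,
                   file.path(out_dir, paste0(prefix, "_nodes.csv")))
  readr::write_csv(result$segments,
                   file.path(out_dir, paste0(prefix, "_segments.csv")))
  readr::write_csv(result$outlets,
                   file.path(out_dir, paste0(prefix, "_outlets.csv")))
  invisible(out_dir)
}
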