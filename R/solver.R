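#' Solve nodal pressures on a conductance network
#'
#' Kirchhoff mass balance \eqn{\sum_j G_{ij}(P_i - P_j) = Q_i} assembled as
#' a weighted graph Laplacian and solved with a sparse direct (LU)
#' factorization. Nodes listed in `dirichlet` are pinned to their
#' prescribed pressures; all other nodes receive the (default zero) source
#' terms.
#'
#' @param network a discretized `vascular_network` (see
#'   [discretize_network()]), or any list with a `segments` tibble
#'   (`from`, `to`) and a `nodes` tibble (`id`).
#' @param conductance numeric vector of segment conductances, SI
#'   (m^3 Pa^-1 s^-1), aligned with `network$segments`.
#' @param dirichlet tibble/data frame with columns `node` and
#'   `pressure_Pa`.
#' @param source optional numeric vector of nodal source terms (m^3/s)
#'   aligned with `network$nodes`; defaults to zero.
#' @return Tibble with `id` and `pressure_Pa` for every node.
#' @export
solve_pressures <- function(network, conductance, dirichlet, source = NULL) {
  segs <- network$segments
  if (is.null(segs)) stop("network must be discretized first (see discretize_network())",
                          call. = FALSE)
  node_ids <- network$nodes$id
  n <- length(node_ids)
  from <- match(segs$from, node_ids)
  to <- match(segs$to, node_ids)
  fixed <- match(dirichlet$node, node_ids)
  if (anyNA(fixed)) stop("dirichlet refers to unknown node ids", call. = FALSE)
  if (is.null(source)) source <- numeric(n)
  P <- laplacian_solve(n, from, to, conductance, fixed, dirichlet$pressure_Pa,
                       source)
  tibble::tibble(id = node_ids, pressure_Pa = P)
}

# Sparse-LU solve of the pinned Laplacian system. Returns the full nodal
# pressure vector. A structurally singular reduced system (a component
# with no pinned node) is reported with the ids of one offending
# component.
laplacian_solve <- function(n, from, to, G, fixed_idx, fixed_val, source) {
  L <- Matrix::sparseMatrix(
    i = c(from, to, from, to),
    j = c(to, from, from, to),
    x = c(-G, -G, G, G),
    dims = c(n, n)
  )
  U <- setdiff(seq_len(n), fixed_idx)
  A <- L[U, U, drop = FALSE]
  rhs <- source[U] - as.numeric(L[U, fixed_idx, drop = FALSE] %*% fixed_val)
  P <- numeric(n)
  P[fixed_idx] <- fixed_val
  if (length(U) > 0L) {
    PU <- tryCatch(
      as.numeric(Matrix::solve(A, rhs)),
      error = function(e) {
        comp <- find_unpinned_component(n, from, to, G, fixed_idx)
        stop("singular pressure system: nodes {",
             paste(utils::head(comp, 8), collapse = ", "),
             if (length(comp) > 8) ", ..." else "",
             "} form a component with no pressure boundary",
             call. = FALSE)
      })
    P[U] <- PU
  }
  P
}

find_unpinned_component <- function(n, from, to, G, fixed_idx) {
  keep <- G > 0
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  pinned_comps <- unique(comp[fixed_idx])
  bad <- which(!(comp %in% pinned_comps))
  if (length(bad) == 0L) bad <- seq_len(n) # numerical rather than structural
  bad
}

# Precompute index structures shared by every solve on one network.
prepare_solver <- function(network, config) {
  segs <- network$segments
  if (is.null(segs)) stop("network must be discretized first (see discretize_network())",
                          call. = FALSE)
  node_ids <- network$nodes$id
  n <- length(node_ids)
  from <- match(segs$from, node_ids)
  to <- match(segs$to, node_ids)
  inlet <- which(network$nodes$role == "inlet")
  if (length(inlet) != 1L) stop("network must have exactly one inlet node", call. = FALSE)
  outlet_nodes <- which(network$nodes$role == "outlet")
  is_outlet_seg <- segs$type == "outlet"
  # outlet segments in the order of network$outlets, body outlet last
  outlet_seg_rows <- match(network$outlets$vessel, segs$vessel_id[is_outlet_seg])
  outlet_seg_rows <- which(is_outlet_seg)[outlet_seg_rows]
  body_seg_row <- which(is_outlet_seg & segs$territory == "systemic")
  pial_rows <- match(network$outlets$pial_node, node_ids)
  if (!"G_fixed_SI" %in% names(segs)) segs$G_fixed_SI <- NA_real_
  elastic <- !is_outlet_seg & is.na(segs$G_fixed_SI)
  h_mm <- wall_thickness(segs$r0_mm)
  list(
    segs = segs, n = n, node_ids = node_ids, from = from, to = to,
    inlet = inlet, outlet_nodes = outlet_nodes,
    outlet_seg_rows = outlet_seg_rows, body_seg_row = body_seg_row,
    pial_rows = pial_rows, elastic = elastic, h_mm = h_mm,
    is_outlet_seg = is_outlet_seg
  )
}

# Conductance vector (SI) for a given radius state and outlet resistances.
segment_conductances <- function(sv, r_mm, outlet_R, body_R, config) {
  segs <- sv$segs
  sol <- config$solver
  G <- numeric(nrow(segs))
  norm_seg <- !sv$is_outlet_seg & is.na(segs$G_fixed_SI)
  G[norm_seg] <- vessel_conductance(r_mm[norm_seg], segs$length_mm[norm_seg],
                                    sol$viscosity_Pa_s, sol$zeta)
  fx <- which(!is.na(segs$G_fixed_SI))
  G[fx] <- segs$G_fixed_SI[fx]
  G[sv$outlet_seg_rows] <- 1 / (outlet_R * PASML_TO_PASM3)
  if (length(sv$body_seg_row) == 1L) {
    G[sv$body_seg_row] <- 1 / (body_R * PASML_TO_PASM3)
  }
  G
}

pressure_norm <- function(P, P_prev, kind) {
  if (kind == "component") {
    max(abs(P - P_prev) / pmax(abs(P), .Machine$double.eps))
  } else {
    max(abs(P - P_prev)) / max(abs(P))
  }
}

#' Steady-state compliant-vessel flow solution
#'
#' Fixed-point iteration coupling the Kirchhoff pressure solve to the
#' elastic pressure-area law: pressures are solved with conductances from
#' the previous radii, radii are then updated from the new segment
#' pressures (with under-relaxation), until the relative pressure change
#' falls below `solver.pressure_tol` (default 1e-6). The converged state
#' satisfies both the mass balance and the pressure-area relation
#' simultaneously.
#'
#' @param network a discretized, outlet-initialized `vascular_network`
#'   (outlet resistances from [calibrate_network()] / [autoregulate()] or
#'   passed explicitly).
#' @param config a [model_config()].
#' @param outlet_R numeric vector of pial outlet resistances, Pa s/ml, in
#'   the order of `network$outlets`; defaults to the stored values.
#' @param body_R extracranial outlet resistance, Pa s/ml.
#' @param init_radii_mm optional warm-start segment radii.
#' @return A `bf_result`: tibbles `nodes` (id, pressure_Pa), `segments`
#'   (flow, velocity, radius), `outlets` (flow, resistance, pial pressure),
#'   plus `diagnostics` (iterations, residuals, inlet flow/pressure).
#' @export
simulate_flow <- function(network, config = network$meta$config,
                          outlet_R = network$outlets$resistance_Pa_s_ml,
                          body_R = network$meta$body_outlet_R,
                          init_radii_mm = NULL) {
  sv <- prepare_solver(network, config)
  st <- elastic_fixed_point(sv, config, outlet_R, body_R, init_radii_mm)
  build_result(network, sv, st, config, outlet_R, body_R)
}

elastic_fixed_point <- function(sv, config, outlet_R, body_R,
                                init_radii_mm = NULL) {
  sol <- config$solver
  segs <- sv$segs
  if (any(is.na(outlet_R)) || (length(sv$body_seg_row) == 1L && is.na(body_R))) {
    stop("outlet resistances are not initialized; run calibrate_network() first or pass outlet_R/body_R",
         call. = FALSE)
  }
  r <- if (is.null(init_radii_mm)) segs$r0_mm else init_radii_mm
  dirichlet_idx <- c(sv$inlet, sv$outlet_nodes)
  dirichlet_val <- c(sol$inlet_pressure_Pa,
                     rep(sol$outlet_pressure_Pa, length(sv$outlet_nodes)))
  P <- NULL
  eps <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    G <- segment_conductances(sv, r, outlet_R, body_R, config)
    P_new <- laplacian_solve(sv$n, sv$from, sv$to, G, dirichlet_idx,
                             dirichlet_val, numeric(sv$n))
    if (!is.null(P)) eps <- pressure_norm(P_new, P, sol$norm)
    P <- P_new
    if (eps < sol$pressure_tol && it >= 2L) break
    if (it >= sol$max_iterations) {
      stop(sprintf("elastic iteration did not converge: eps_P = %.3e after %d iterations",
                   eps, it), call. = FALSE)
    }
    # radius update from the mean segment pressure, under-relaxed
    el <- sv$elastic
    P_seg <- (P[sv$from[el]] + P[sv$to[el]]) / 2
    r_target <- radius_from_pressure(P_seg, sol$reference_pressure_Pa,
                                     segs$r0_mm[el], segs$E_Pa[el],
                                     sol$poisson, sv$h_mm[el])
    r[el] <- r[el] + sol$relaxation * (r_target - r[el])
  }
  G <- segment_conductances(sv, r, outlet_R, body_R, config)
  Q_SI <- G * (P[sv$from] - P[sv$to])
  list(P = P, r = r, G = G, Q_SI = Q_SI, iterations = it, eps_P = eps)
}

build_result <- function(network, sv, st, config, outlet_R, body_R,
                         autoreg = NULL) {
  segs <- sv$segs
  Q_ml <- st$Q_SI / ML_TO_M3
  r_m <- st$r * MM_TO_M
  v_mm_s <- ifelse(sv$is_outlet_seg, NA_real_,
                   st$Q_SI / (pi * r_m^2) / MM_TO_M)
  inlet_Q <- inlet_flow(sv, st)
  # mass-balance residual at free nodes
  net_flux <- numeric(sv$n)
  net_flux <- net_flux +
    as.numeric(tapply(st$Q_SI, factor(sv$from, levels = seq_len(sv$n)), sum, default = 0)) -
    as.numeric(tapply(st$Q_SI, factor(sv$to, levels = seq_len(sv$n)), sum, default = 0))
  free <- setdiff(seq_len(sv$n), c(sv$inlet, sv$outlet_nodes))
  mass_resid <- if (length(free) > 0L) {
    max(abs(net_flux[free])) / (inlet_Q * ML_TO_M3)
  } else 0
  outlet_flow <- Q_ml[sv$outlet_seg_rows]
  res <- list(
    nodes = tibble::tibble(id = sv$node_ids, pressure_Pa = st$P),
    segments = tibble::tibble(
      seg_id = segs$seg_id, vessel_id = segs$vessel_id,
      from = segs$from, to = segs$to, type = segs$type,
      territory = segs$territory,
      radius_mm = ifelse(sv$is_outlet_seg, NA_real_, st$r),
      flow_ml_s = Q_ml, velocity_mm_s = v_mm_s
    ),
    outlets = tibble::tibble(
      node = network$outlets$node,
      pial_node = network$outlets$pial_node,
      territory = network$outlets$territory,
      flow_ml_s = outlet_flow,
      resistance_Pa_s_ml = outlet_R,
      pial_pressure_Pa = st$P[sv$pial_rows]
    ),
    body = list(resistance_Pa_s_ml = body_R,
                flow_ml_s = if (length(sv$body_seg_row) == 1L)
                  Q_ml[sv$body_seg_row] else NA_real_),
    diagnostics = list(
      elastic_iterations = st$iterations,
      eps_P = st$eps_P,
      mass_residual = mass_resid,
      inlet_flow_ml_s = inlet_Q,
      inlet_pressure_Pa = st$P[sv$inlet],
      autoregulation = autoreg
    ),
    radii_mm = st$r,
    network = network,
    config = config
  )
  class(res) <- "bf_result"
  res
}

inlet_flow <- function(sv, st) {
  out_of_inlet <- sum(st$Q_SI[sv$from == sv$inlet]) -
    sum(st$Q_SI[sv$to == sv$inlet])
  out_of_inlet / ML_TO_M3
}

#' @export
print.bf_result <- function(x, ...) {
  d <- x$diagnostics
  cat("<bf_result>\n")
  cat(sprintf("  inlet: %.6g ml/s at %.6g Pa\n", d$inlet_flow_ml_s,
              d$inlet_pressure_Pa))
  cat(sprintf("  pial outlet flow: total %.6g ml/s over %d outlets\n",
              sum(x$outlets$flow_ml_s), nrow(x$outlets)))
  cat(sprintf("  elastic iterations: %d (eps_P = %.2e, mass residual = %.2e)\n",
              d$elastic_iterations, d$eps_P, d$mass_residual))
  if (!is.null(d$autoregulation)) {
    cat(sprintf("  autoregulation: %d iterations (eps_R = %.2e, %d clamped)\n",
                d$autoregulation$iterations, d$autoregulation$eps_R,
                sum(x$outlets$clamped != "none")))
  }
  invisible(x)
}

#' Per-segment flow and velocity from a converged solution
#'
#' Flow is \eqn{Q_{ij} = G_{ij}(P_i - P_j)} (antisymmetric under endpoint
#' swap); velocity divides by the mean-radius cross-section
#' \eqn{\pi ((r_i + r_j)/2)^2}.
#'
#' @param result a `bf_result`.
#' @return Tibble `seg_id`, `flow_ml_s`, `velocity_mm_s`.
#' @export
segment_flow_and_velocity <- function(result) {
  result$segments[, c("seg_id", "flow_ml_s", "velocity_mm_s")]
}

#' Calibrate outlet resistances to the inlet boundary conditions
#'
#' With the inlet pinned at the systolic working pressure, all outlet
#' resistances (pial and extracranial) are scaled by a common factor and
#' the full compliant system re-solved until the simulated inlet flow
#' matches the target cardiac output to `solver.bc_tol` (default 1e-6
#' relative); the inlet pressure condition then holds exactly. Pial outlet
#' resistances are initialized at the autoregulation set-point
#' `(p_in - p_out) / (Q_brain / N_total)`; the initialization is erased by
#' the uniform scaling (calibration is initialization-independent).
#'
#' Calibration runs on the healthy network, before autoregulation and
#' before any thrombus is applied.
#'
#' @param network a discretized `vascular_network`.
#' @param config a [model_config()].
#' @param max_iter maximum scaling iterations.
#' @return The network with calibrated `outlets$resistance_Pa_s_ml`,
#'   `meta$body_outlet_R`, a stored radius state for warm starts, and
#'   `meta$calibration` diagnostics.
#' @export
calibrate_network <- function(network, config = network$meta$config,
                              max_iter = 60L) {
  if (is.null(network$segments)) network <- discretize_network(network)
  sol <- config$solver
  aut <- config$autoregulation
  sv <- prepare_solver(network, config)
  if (any(!is.na(sv$segs$G_fixed_SI))) {
    stop("calibrate_network must run on the healthy network (no thrombus)",
         call. = FALSE)
  }
  N_total <- nrow(network$outlets)
  q <- aut$Q_brain_ml_s / N_total
  dp <- sol$inlet_pressure_Pa - sol$outlet_pressure_Pa
  outlet_R <- network$outlets$resistance_Pa_s_ml
  if (any(is.na(outlet_R))) outlet_R <- rep(dp / q, N_total)
  body_R <- network$meta$body_outlet_R
  if (is.null(body_R) || is.na(body_R)) {
    body_R <- dp / max(sol$inlet_flow_ml_s - aut$Q_brain_ml_s, 1e-9)
  }
  radii <- NULL
  mismatch <- Inf
  history <- numeric()
  for (it in seq_len(max_iter)) {
    st <- elastic_fixed_point(sv, config, outlet_R, body_R, radii)
    radii <- st$r
    Q0 <- inlet_flow(sv, st)
    mismatch <- abs(Q0 / sol$inlet_flow_ml_s - 1)
    history <- c(history, mismatch)
    if (mismatch < sol$bc_tol) break
    s <- Q0 / sol$inlet_flow_ml_s
    outlet_R <- outlet_R * s
    body_R <- body_R * s
  }
  if (mismatch >= sol$bc_tol) {
    stop(sprintf("boundary calibration did not converge: |Q0/Qin - 1| = %.3e after %d iterations",
                 mismatch, max_iter), call. = FALSE)
  }
  network$outlets$resistance_Pa_s_ml <- outlet_R
  network$meta$body_outlet_R <- body_R
  network$meta$calibration <- list(iterations = length(history),
                                   mismatch = mismatch, history = history)
  network$state <- list(radii_mm = radii)
  network
}
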