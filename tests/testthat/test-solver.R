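test_that("two equal conductances in series put the midpoint at the mean", {
  net <- list(nodes = tibble::tibble(id = 1:3),
              segments = tibble::tibble(from = c(1L, 2L), to = c(2L, 3L)))
  P <- solve_pressures(net, conductance = c(2, 2),
                       dirichlet = tibble::tibble(node = c(1L, 3L),
                                                  pressure_Pa = c(100, 0)))
  expect_equal(P$pressure_Pa, c(100, 50, 0))
})

test_that("sparse solve matches a dense oracle on random networks", {
  for (seed in 1:3) {
    rc <- random_conductance_network(20, seed = seed)
    fixed <- tibble::tibble(node = c(1L, 20L), pressure_Pa = c(1000, 10))
    P <- solve_pressures(rc$network, rc$G, fixed)$pressure_Pa
    oracle <- dense_pressure_oracle(20, rc$from, rc$to, rc$G,
                                    c(1, 20), c(1000, 10))
    expect_equal(P, oracle, tolerance = 1e-10)
    # maximum principle: interior pressures within the boundary range
    expect_true(all(P >= 10 - 1e-9 & P <= 1000 + 1e-9))
  }
})

test_that("equal boundary pressures give a uniform field with zero flow", {
  rc <- random_conductance_network(30, seed = 4)
  fixed <- tibble::tibble(node = c(1L, 30L), pressure_Pa = c(500, 500))
  P <- solve_pressures(rc$network, rc$G, fixed)$pressure_Pa
  expect_equal(P, rep(500, 30), tolerance = 1e-12)
})

test_that("a component without pressure boundary is reported as singular", {
  net <- list(nodes = tibble::tibble(id = 1:4),
              segments = tibble::tibble(from = c(1L, 3L), to = c(2L, 4L)))
  expect_error(
    solve_pressures(net, c(1, 1),
                    tibble::tibble(node = 1L, pressure_Pa = 100)),
    "no pressure boundary")
})

test_that("the rigid limit reduces to a single linear solve", {
  cfg <- model_config()
  net <- line_network(E_Pa = 1e15, config = cfg)
  res <- simulate_flow(net, cfg, outlet_R = 1e5, body_R = NULL)
  expect_lte(res$diagnostics$elastic_iterations, 2L)
  # identical to the pure linear solve at reference radii
  G0 <- vessel_conductance(net$segments$r0_mm, net$segments$length_mm,
                           cfg$solver$viscosity_Pa_s, cfg$solver$zeta)
  G0[net$segments$type == "outlet"] <- 1e-6 / 1e5
  lin <- solve_pressures(net, G0, tibble::tibble(
    node = c(1L, max(net$nodes$id)),
    pressure_Pa = c(cfg$solver$inlet_pressure_Pa,
                    cfg$solver$outlet_pressure_Pa)))
  expect_equal(res$nodes$pressure_Pa, lin$pressure_Pa, tolerance = 1e-9)
})

test_that("the compliant fixed point satisfies both laws and is start-independent", {
  # tight tolerance so the coupled residual reaches the elastic law's scale
  cfg <- model_config("solver.pressure_tol" = 1e-13)
  net <- line_network(n_seg = 4, r0_mm = 0.5, L_mm = 5, E_Pa = 1.6e6,
                      config = cfg)
  res <- simulate_flow(net, cfg, outlet_R = 1e5, body_R = NULL)
  sol <- cfg$solver
  el <- res$segments$type != "outlet"
  P_seg <- (res$nodes$pressure_Pa[match(res$segments$from[el], res$nodes$id)] +
            res$nodes$pressure_Pa[match(res$segments$to[el], res$nodes$id)]) / 2
  # pressure implied by the elastic law at the converged radii
  r0 <- net$segments$r0_mm[el]
  h <- wall_thickness(r0)
  P_implied <- sol$reference_pressure_Pa +
    (res$segments$radius_mm[el] - r0) * 1e-3 *
    net$segments$E_Pa[el] * h * 1e-3 /
    ((r0 * 1e-3)^2 * (1 - sol$poisson^2))
  expect_equal(length(P_implied), sum(el))
  expect_lt(max(abs(P_implied - P_seg)), 1e-9 * sol$reference_pressure_Pa)
  # same fixed point from perturbed initial radii
  res2 <- simulate_flow(net, cfg, outlet_R = 1e5, body_R = NULL,
                        init_radii_mm = net$segments$r0_mm * 1.1)
  res3 <- simulate_flow(net, cfg, outlet_R = 1e5, body_R = NULL,
                        init_radii_mm = net$segments$r0_mm * 0.9)
  expect_equal(res2$nodes$pressure_Pa, res3$nodes$pressure_Pa,
               tolerance = 1e-10)
  expect_equal(res2$segments$radius_mm, res3$segments$radius_mm,
               tolerance = 1e-10)
})

test_that("the converged answer is relaxation-independent", {
  cfg1 <- model_config("solver.pressure_tol" = 1e-12,
                       "solver.relaxation" = 0.5)
  cfg2 <- model_config("solver.pressure_tol" = 1e-12,
                       "solver.relaxation" = 0.9)
  net <- line_network(n_seg = 3, r0_mm = 0.5, L_mm = 5)
  r1 <- simulate_flow(net, cfg1, outlet_R = 1e5, body_R = NULL)
  r2 <- simulate_flow(net, cfg2, outlet_R = 1e5, body_R = NULL)
  expect_equal(r1$nodes$pressure_Pa, r2$nodes$pressure_Pa, tolerance = 1e-9)
})

test_that("flows are conductance times pressure drop and conserve mass", {
  res <- small_healthy()
  # Q = G dP on a spot-check segment (healthy, non-outlet)
  segs <- res$network$segments
  i <- which(segs$type == "pial")[1]
  G <- vessel_conductance(res$segments$radius_mm[i], segs$length_mm[i],
                          model_config()$solver$viscosity_Pa_s, 9)
  dP <- res$nodes$pressure_Pa[match(segs$from[i], res$nodes$id)] -
    res$nodes$pressure_Pa[match(segs$to[i], res$nodes$id)]
  expect_equal(res$segments$flow_ml_s[i], G * dP / 1e-6, tolerance = 1e-9)
  # global conservation: inlet flow equals summed outlet flows
  total_out <- sum(res$outlets$flow_ml_s) + res$body$flow_ml_s
  expect_equal(res$diagnostics$inlet_flow_ml_s, total_out, tolerance = 1e-8)
  expect_lt(res$diagnostics$mass_residual, 1e-8)
  # velocity uses the mean-radius cross-section
  v <- res$segments$flow_ml_s[i] * 1e-6 /
    (pi * (res$segments$radius_mm[i] * 1e-3)^2) * 1e3
  expect_equal(res$segments$velocity_mm_s[i], v)
})

test_that("boundary calibration hits both inlet conditions and is start-independent", {
  net <- small_calibrated()
  cfg <- small_config()
  res <- simulate_flow(net, cfg)
  expect_equal(res$diagnostics$inlet_pressure_Pa, 12500)
  expect_lt(abs(res$diagnostics$inlet_flow_ml_s / 100 - 1), 1e-6)
  # doubling the initial outlet resistances leads to the same calibrated state
  net0 <- small_network()
  q <- target_outlet_flow(cfg, nrow(net0$outlets))
  net0$outlets$resistance_Pa_s_ml <-
    2 * (cfg$solver$inlet_pressure_Pa - cfg$solver$outlet_pressure_Pa) / q
  net0$meta$body_outlet_R <- 2 * (cfg$solver$inlet_pressure_Pa -
                                    cfg$solver$outlet_pressure_Pa) / 87.5
  alt <- calibrate_network(net0, cfg)
  expect_equal(alt$outlets$resistance_Pa_s_ml,
               net$outlets$resistance_Pa_s_ml, tolerance = 1e-5)
})

test_that("calibration refuses a thrombosed network", {
  net <- apply_thrombus(small_calibrated(),
                        thrombus_spec(length_mm = 5, permeability_mm2 = 1e-6))
  expect_error(calibrate_network(net, small_config()), "healthy")
})
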