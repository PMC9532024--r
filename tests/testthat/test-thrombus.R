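test_that("Darcy resistance is the SI quotient mu L / (kappa A)", {
  # direct SI evaluation: kappa 1e-5 mm^2, A 4.5 mm^2, L 10 mm
  oracle <- 3.5e-3 * 10e-3 / ((1e-5 * 1e-6) * (4.5 * 1e-6)) / 1e6
  expect_equal(darcy_resistance(1e-5, 4.5, 10), oracle)
  expect_equal(oracle, 7.78e5, tolerance = 1e-3)
  # halving permeability doubles resistance exactly
  expect_equal(darcy_resistance(5e-6, 4.5, 10), 2 * oracle)
  # limits: impermeable is the Inf sentinel, high permeability vanishes
  expect_identical(darcy_resistance(0, 4.5, 10), Inf)
  expect_lt(darcy_resistance(1e9, 4.5, 10), 1e-8)
  expect_error(darcy_resistance(1e-5, -1, 10), "positive")
  expect_error(darcy_resistance(-1e-5, 1, 10), "non-negative")
})

test_that("total segment resistance is the series sum with the host vessel", {
  net <- small_network()
  cfg <- small_config()
  host <- net$vessels[!is.na(net$vessels$name) &
                        net$vessels$name == "root_R-MCA", ]
  R_ves <- vessel_resistance(host$r0_mm, host$length_mm,
                             cfg$solver$viscosity_Pa_s, cfg$solver$zeta)
  # highly permeable clot: R_T collapses to the vessel resistance
  R_T <- thrombus_resistance(thrombus_spec(length_mm = 10,
                                           permeability_mm2 = 1e6),
                             net, cfg)
  expect_equal(R_T, R_ves, tolerance = 1e-6)
  # series positivity
  kappas <- 10^seq(-8, -3)
  Rs <- vapply(kappas, function(k)
    thrombus_resistance(thrombus_spec(length_mm = 10, permeability_mm2 = k),
                        net, cfg), numeric(1))
  A <- pi * host$r0_mm^2
  R_darcy <- darcy_resistance(kappas, A, 10, cfg$solver$viscosity_Pa_s)
  expect_true(all(Rs >= pmax(R_darcy, R_ves)))
  expect_equal(Rs, R_darcy + R_ves)
  # thrombus dominance at low permeability
  expect_equal(Rs[1] / R_darcy[1], 1, tolerance = 1e-3)
  # a clot longer than its host vessel is rejected
  expect_error(thrombus_resistance(
    thrombus_spec(length_mm = host$length_mm + 1, permeability_mm2 = 1e-5),
    net, cfg), "longer than")
  expect_error(thrombus_resistance(thrombus_spec("no_such_vessel",
                                                 length_mm = 1,
                                                 permeability_mm2 = 1),
                                   net, cfg), "not found")
})

test_that("an extremely permeable clot reproduces healthy flows", {
  healthy <- small_healthy()
  ghost <- simulate_stroke(healthy$network,
                           thrombus_spec(length_mm = 10,
                                         permeability_mm2 = 1e4),
                           small_config(), baseline = healthy)
  expect_equal(ghost$outlets$flow_ml_s, healthy$outlets$flow_ml_s,
               tolerance = 1e-6)
  expect_equal(ghost$infarct_ml, 0)
})

test_that("the measured pressure drop over the clot obeys Ohm's identity", {
  healthy <- small_healthy()
  s <- simulate_stroke(healthy$network,
                       thrombus_spec(length_mm = 10, permeability_mm2 = 1e-5),
                       small_config(), baseline = healthy)
  expect_equal(s$thrombus$dp_Pa,
               s$thrombus$Q_thrombus_ml_s * s$thrombus$R_T_Pa_s_ml,
               tolerance = 1e-8)
})

test_that("full occlusion leaves only collateral supply to the territory", {
  healthy <- small_healthy()
  s <- simulate_stroke(healthy$network,
                       thrombus_spec(length_mm = 10, permeability_mm2 = 0),
                       small_config(), baseline = healthy)
  expect_identical(s$thrombus$Q_thrombus_ml_s, 0)
  expect_equal(s$thrombus$Q_total_ml_s, s$thrombus$Q_collateral_ml_s)
  expect_gt(s$infarct_ml, 0)
  # with zero collaterals the territory receives nothing at all
  cfg0 <- small_config()
  cfg0$network$collateral_probability <- 0
  net0 <- calibrate_network(discretize_network(generate_network(cfg0)), cfg0)
  h0 <- autoregulate(net0, cfg0)
  s0 <- simulate_stroke(h0$network,
                        thrombus_spec(length_mm = 10, permeability_mm2 = 0),
                        cfg0, baseline = h0)
  expect_equal(s0$thrombus$Q_total_ml_s, 0, tolerance = 1e-9)
  rmca <- s0$outlets$territory == "R-MCA"
  expect_true(all(s0$outlets$flow_ml_s[rmca] < 1e-9))
})

test_that("equal segment resistance collapses (kappa, L) pairs to one response", {
  healthy <- small_healthy()
  cfg <- small_config()
  net <- healthy$network
  host <- net$vessels[!is.na(net$vessels$name) &
                        net$vessels$name == "root_R-MCA", ]
  A <- pi * host$r0_mm^2
  mu <- cfg$solver$viscosity_Pa_s
  R_ves <- vessel_resistance(host$r0_mm, host$length_mm, mu, cfg$solver$zeta)
  for (R_target in c(1e4, 1e6)) {
    out <- lapply(c(3, 28), function(L) {
      kappa <- mu * (L * 1e-3) / ((A * 1e-6) * ((R_target - R_ves) * 1e6)) / 1e-6
      s <- simulate_stroke(net, thrombus_spec(length_mm = L,
                                              permeability_mm2 = kappa),
                           cfg, baseline = healthy)
      expect_equal(s$thrombus$R_T_Pa_s_ml, R_target, tolerance = 1e-12)
      c(s$thrombus$dp_Pa, s$thrombus$Q_thrombus_ml_s)
    })
    expect_equal(out[[1]], out[[2]], tolerance = 1e-9)
  }
})

test_that("flow and pressure drop respond monotonically to permeability", {
  healthy <- small_healthy()
  cfg <- small_config()
  kappas <- 10^seq(-7, -3, length.out = 6)
  runs <- lapply(kappas, function(k)
    simulate_stroke(healthy$network,
                    thrombus_spec(length_mm = 10, permeability_mm2 = k),
                    cfg, baseline = healthy))
  Q <- vapply(runs, function(s) s$thrombus$Q_thrombus_ml_s, numeric(1))
  dp <- vapply(runs, function(s) s$thrombus$dp_Pa, numeric(1))
  expect_true(all(diff(Q) > 0))
  expect_true(all(diff(dp) < 0))
})

test_that("sweeps tabulate the grid long-form and survive failures", {
  cfg <- small_config()
  sw <- sweep_thrombus(thrombus_lengths_mm = 10,
                       permeabilities_mm2 = c(1e-6, 1e-4),
                       collateral_probabilities = 0.25, seeds = 1,
                       config = cfg)
  expect_equal(nrow(sw), 2)
  expect_true(all(is.na(sw$error)))
  expect_true(all(c("seed", "collateral_probability", "L_mm", "kappa_mm2",
                    "R_T_Pa_s_ml", "dp_Pa", "Q_thrombus_ml_s",
                    "Q_collateral_ml_s", "Q_total_ml_s", "infarct_ml")
                  %in% names(sw)))
  # a bad host vessel is recorded as a per-point error, not a crash
  sw_bad <- sweep_thrombus(10, 1e-5, 0.25, 1, config = cfg,
                           vessel = "no_such_vessel")
  expect_false(any(is.na(sw_bad$error)))
})

test_that("interrupted sweeps resume from completed grid points", {
  cfg <- small_config()
  dir <- withr::local_tempdir()
  sw1 <- sweep_thrombus(10, c(1e-6, 1e-4), 0.25, 1, config = cfg,
                        out_dir = dir)
  files <- list.files(dir, pattern = "^grid_")
  expect_equal(length(files), 2)
  # delete one point and rerun: identical table, only the missing point redone
  unlink(file.path(dir, files[2]))
  sw2 <- sweep_thrombus(10, c(1e-6, 1e-4), 0.25, 1, config = cfg,
                        out_dir = dir)
  expect_equal(as.data.frame(sw2), as.data.frame(sw1), tolerance = 1e-12)
})
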