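test_that("measured flow is void fraction times lumen volume rate", {
  m <- tibble::tibble(patient_id = "P001", transit_time_s = 5,
                      void_fraction = 0.2, length_mm = 10,
                      lumen_area_mm2 = 4.5)
  out <- flow_from_measurement(m)
  expect_equal(out$flow_ml_s, 0.2 * 4.5 * 10 / 5 / 1000) # 1.8 mm^3/s
  expect_equal(out$flow_ml_s, 1.8e-3)
  # zero void fraction is a valid, fully impervious measurement
  m$void_fraction <- 0
  expect_equal(flow_from_measurement(m)$flow_ml_s, 0)
  # doubling transit time halves flow
  m$void_fraction <- 0.2
  m2 <- m; m2$transit_time_s <- 10
  expect_equal(flow_from_measurement(m2)$flow_ml_s,
               flow_from_measurement(m)$flow_ml_s / 2)
  expect_error(flow_from_measurement(dplyr::select(m, -"void_fraction")),
               "missing column")
  m$transit_time_s <- -1
  expect_error(flow_from_measurement(m), "positive")
})

test_that("synthetic cohorts are reproducible and physiologically ranged", {
  a <- generate_synthetic_cohort(44, seed = 3)
  b <- generate_synthetic_cohort(44, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a), 44)
  expect_true(all(a$length_mm >= 3 & a$length_mm <= 28))
  expect_true(all(a$transit_time_s >= 1 & a$transit_time_s <= 30))
  expect_true(all(a$void_fraction >= 0 & a$void_fraction <= 0.5))
  expect_true(all(a$lumen_area_mm2 >= 3 & a$lumen_area_mm2 <= 8))
  c2 <- generate_synthetic_cohort(10, ranges = list(length_mm = c(5, 6)),
                                  seed = 1)
  expect_true(all(c2$length_mm >= 5 & c2$length_mm <= 6))
  expect_error(generate_synthetic_cohort(5, ranges = list(bogus = c(1, 2))),
               "unknown range")
})

curve_fixture <- function() cached("response_curve", {
  build_response_curve(0.25, config = small_config(), seeds = 1)
})

test_that("the response curve is monotone, bounded by limits, and exact at knots", {
  curve <- curve_fixture()
  tab <- curve$table
  expect_true(all(diff(tab$Q_thrombus_ml_s) <= 0))
  # occlusion limit: flow vanishes as resistance grows
  expect_lt(tab$Q_thrombus_ml_s[nrow(tab)], 1e-4)
  # healthy limit: lowest resistance approaches the healthy vessel flow
  expect_equal(tab$Q_thrombus_ml_s[1], curve$healthy_flow_ml_s,
               tolerance = 0.05)
  # inverting a knot's flow returns that knot's resistance
  for (i in c(5, 8, 12)) {
    expect_equal(invert_to_resistance(tab$Q_thrombus_ml_s[i], curve),
                 tab$R_T_Pa_s_ml[i], tolerance = 1e-9)
  }
  # monotone inversion: larger flow, smaller resistance
  R <- invert_to_resistance(c(0.001, 0.01, 0.1), curve)
  expect_true(all(diff(R) < 0))
  # zero flow maps to the fully occluding branch
  expect_identical(invert_to_resistance(0, curve), Inf)
  expect_error(invert_to_resistance(10 * curve$healthy_flow_ml_s, curve),
               "healthy branch")
  expect_error(build_response_curve(0.25, resistance_grid_Pa_s_ml = c(1, 10),
                                    config = small_config()), "4 decades")
})

test_that("permeability-resistance conversion is an exact algebraic inverse", {
  mu <- 3.5e-3; A <- 4.5; L <- 12; R_ves <- 150
  kappas <- 10^seq(-7, -4, length.out = 7)
  R_T <- darcy_resistance(kappas, A, L, mu) + R_ves
  back <- permeability_from_resistance(R_T, L, A, mu, R_ves)
  expect_equal(back, kappas, tolerance = 1e-12)
  # the worked example inverts to its generating permeability
  expect_equal(permeability_from_resistance(7.78e5, 10, 4.5), 1e-5,
               tolerance = 1e-3)
  expect_warning(out <- permeability_from_resistance(100, L, A, mu, 150))
  expect_identical(out, Inf)
  expect_identical(permeability_from_resistance(Inf, L, A, mu, R_ves), 0)
})

test_that("forward-simulated patients invert back to their resistance", {
  curve <- curve_fixture()
  healthy <- small_healthy()
  cfg <- small_config()
  for (kap in c(3e-6, 3e-5)) {
    th <- thrombus_spec(length_mm = 14, permeability_mm2 = kap)
    s <- simulate_stroke(healthy$network, th, cfg, baseline = healthy)
    R_rec <- invert_to_resistance(s$thrombus$Q_thrombus_ml_s, curve)
    expect_equal(R_rec, s$thrombus$R_T_Pa_s_ml, tolerance = 0.02)
  }
})

test_that("cohort estimation chains measurement to permeability and infarct", {
  curve <- curve_fixture()
  cfg <- small_config()
  cohort <- generate_synthetic_cohort(12, seed = 9)
  cohort$void_fraction[1] <- 0 # fully impervious patient
  est <- suppressWarnings(estimate_patients(cohort, curve, cfg))
  expect_equal(nrow(est), 12)
  expect_true(all(c("flow_ml_s", "R_T_Pa_s_ml", "dp_mmHg", "kappa_mm2",
                    "infarct_ml") %in% names(est)))
  # impervious branch: occlusive reference values
  expect_identical(est$R_T_Pa_s_ml[1], Inf)
  expect_equal(est$kappa_mm2[1], 0)
  expect_equal(est$infarct_ml[1], curve$occlusive$infarct_ml)
  expect_equal(est$dp_mmHg[1], pa_to_mmhg(curve$occlusive$dp_Pa))
  # pressure drops bounded by the arterio-venous span
  ok <- is.finite(est$dp_mmHg)
  expect_true(all(est$dp_mmHg[ok] > 0))
  expect_true(all(est$dp_mmHg[ok] < pa_to_mmhg(cfg$solver$inlet_pressure_Pa)))
  # monotone chain: larger measured flow, smaller recovered resistance
  fin <- est[is.finite(est$R_T_Pa_s_ml) & !est$clamped, ]
  fin <- fin[order(fin$flow_ml_s), ]
  expect_true(all(diff(fin$R_T_Pa_s_ml) < 0))
})

test_that("estimates survive an SI round trip bit-for-bit", {
  curve <- curve_fixture()
  est <- suppressWarnings(estimate_patients(
    generate_synthetic_cohort(6, seed = 2), curve, small_config()))
  to_SI_and_back <- est$R_T_Pa_s_ml * 1e6 / 1e6
  expect_identical(to_SI_and_back, est$R_T_Pa_s_ml)
  expect_identical(pa_to_mmhg(mmhg_to_pa(est$dp_mmHg)), est$dp_mmHg)
})
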