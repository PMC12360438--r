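test_that("acoustic pressure is MI times the square root of the frequency", {
  expect_equal(acoustic_pressure(sono_pulse(0, 1)), 0)
  expect_equal(acoustic_pressure(sono_pulse(0.4, 1)), 0.4)
  expect_equal(acoustic_pressure(sono_pulse(0.6, 0.25)), 0.3)
  expect_error(sono_pulse(-0.1, 1), "non-negative")
  expect_error(sono_pulse(0.4, 0), "positive")
})

test_that("pore radius law evaluates the fitted quadratic and clamps", {
  law <- pore_law(baseline_pore_radius = 5)
  raw <- pore_radius(0.2, law, clamp = FALSE)
  expect_equal(raw, -14977.9087 * 0.04 + 8208.3947 * 0.2 - 69.0722)
  expect_equal(raw, 973.4904, tolerance = 1e-6)
  # raw polynomial is negative at zero pressure -> clamped to baseline
  expect_lt(pore_radius(0, law, clamp = FALSE), 0)
  expect_equal(pore_radius(0, law), 5)
  # clamping bounds hold on a dense grid
  p <- seq(0, 1, by = 1e-3)
  r <- pore_radius(p, law)
  expect_true(all(r >= law$baseline_pore_radius))
  expect_true(all(r <= law$max_pore_radius))
})

test_that("raw pore polynomial peaks at the vertex, below 1250 nm", {
  law <- pore_law()
  # independent oracle: dense grid scan at 1e-4 MPa resolution
  p <- seq(0, 0.6, by = 1e-4)
  grid_max <- max(pore_radius(p, law, clamp = FALSE))
  vertex <- law$lin_coeff / (2 * abs(law$quad_coeff))
  analytic <- pore_radius(vertex, law, clamp = FALSE)
  expect_equal(grid_max, analytic, tolerance = 1e-6)
  expect_lte(grid_max, 1250)
})

test_that("wall shear stress obeys the exact microstreaming scalings", {
  base <- sono_pulse(0.4, 1)
  tau0 <- wall_shear_stress(base)
  expect_gt(tau0, 0)
  # eta_m = 0 -> no microstreaming
  mb0 <- microbubble_params(wall_displacement_amplitude = 1e-300)
  expect_equal(wall_shear_stress(sono_pulse(0.4, 1, microbubble = mb0)), 0,
               tolerance = 1e-200)
  # doubling eta_m quadruples tau
  mb2 <- microbubble_params(wall_displacement_amplitude = 1e-7)
  expect_equal(wall_shear_stress(sono_pulse(0.4, 1, microbubble = mb2)) / tau0,
               4, tolerance = 1e-12)
  # quadrupling the frequency multiplies tau by 8
  expect_equal(wall_shear_stress(sono_pulse(0.4, 4)) / tau0, 8,
               tolerance = 1e-12)
  # tau ~ 1/R_0 and ~ sqrt(rho mu)
  mbR <- microbubble_params(equilibrium_radius = 3.4e-6)
  expect_equal(wall_shear_stress(sono_pulse(0.4, 1, microbubble = mbR)) / tau0,
               0.5, tolerance = 1e-12)
  mbrm <- microbubble_params(liquid_density = 4 * 1060,
                             liquid_viscosity = 4e-3)
  expect_equal(wall_shear_stress(sono_pulse(0.4, 1, microbubble = mbrm)) / tau0,
               2, tolerance = 1e-12)
})

test_that("shear-stress response quadratics match a Horner oracle", {
  # printed zero-stress values
  expect_identical(proliferation_factor(0), 0.2533)
  expect_identical(apoptosis_factor(0), 0.6666)
  expect_equal(proliferation_factor(10), 0.32, tolerance = 1e-12)
  expect_equal(proliferation_factor(100), 0.8933, tolerance = 1e-12)
  expect_equal(apoptosis_factor(10), 0.7896, tolerance = 1e-12)
  expect_equal(apoptosis_factor(100), 1.6266, tolerance = 1e-12)
  # independent Horner evaluation on random stresses
  horner <- function(tau, a) (a[1] * tau + a[2]) * tau + a[3]
  set.seed(11)
  tau <- runif(100, 0, 300)
  expect_equal(proliferation_factor(tau),
               pmax(horner(tau, c(-3e-6, 0.0067, 0.2533)), 0),
               tolerance = 1e-14)
  expect_equal(apoptosis_factor(tau),
               pmax(horner(tau, c(-3e-5, 0.0126, 0.6666)), 0),
               tolerance = 1e-14)
  # flooring at zero for extreme stress
  expect_identical(apoptosis_factor(1e4), 0)
})

test_that("sono_effect composes the window, pore and stress operations", {
  law <- pore_law()
  p1 <- sono_pulse(0.4, 1, start_time_h = 10, effect_duration_h = 6)
  # before, at entry, inside, just after
  off <- sono_effect(5, list(p1), law)
  expect_equal(off$pore_radius_nm, law$baseline_pore_radius)
  expect_equal(off$tau_Pa, 0)
  on <- sono_effect(10, list(p1), law)
  expect_equal(on$pore_radius_nm, pore_radius(acoustic_pressure(p1), law))
  expect_equal(on$tau_Pa, wall_shear_stress(p1))
  expect_equal(sono_effect(16, list(p1), law), on)   # rectangular envelope
  after <- sono_effect(16.001, list(p1), law)
  expect_equal(after, off)
  # overlapping pulses: maximum effect wins (the fitted quadratic peaks
  # near 0.27 MPa, so the lower-MI pulse dilates pores more here)
  p2 <- sono_pulse(0.2, 1, start_time_h = 12, effect_duration_h = 6)
  both <- sono_effect(13, list(p2, p1), law)
  expect_equal(both$pore_radius_nm,
               max(pore_radius(acoustic_pressure(p1), law),
                   pore_radius(acoustic_pressure(p2), law)))
  # linear envelope decays to baseline at window close
  lin_end <- sono_effect(16, list(p1), law, envelope = "linear")
  expect_equal(lin_end$pore_radius_nm, law$baseline_pore_radius)
  lin_mid <- sono_effect(13, list(p1), law, envelope = "linear")
  expect_equal(lin_mid$tau_Pa, 0.5 * wall_shear_stress(p1))
})
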