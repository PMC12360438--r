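test_that("plasma bolus decays mono-exponentially and superposes", {
  expect_equal(plasma_concentration(10, 10, 24), 1)
  expect_equal(plasma_concentration(34, 10, 24), exp(-1), tolerance = 1e-12)
  expect_equal(plasma_concentration(5, 10, 24), 0)
  # superposition with cap at the plasma ceiling
  two <- plasma_concentration(72, c(0, 72), 24)
  expect_equal(two, min(1, exp(-3) + 1))
  expect_equal(plasma_concentration(73, c(72.5, 73), 24, ceiling = 1), 1)
  expect_error(plasma_concentration(1, 0, 0), "positive")
})

test_that("hindrance coefficients hit exact limits and match an oracle", {
  at0 <- hindrance_coefficients(0)
  expect_equal(at0$H, 1)
  expect_equal(at0$sigma_f, 0)
  expect_equal(at0$Phi, 1)
  at1 <- hindrance_coefficients(1)
  expect_equal(at1$H, 0)
  expect_equal(at1$sigma_f, 1)
  expect_equal(at1$Phi, 0)
  # independent straight-line evaluation of the same published closure
  lam <- 0.5
  Phi <- (1 - lam)^2
  H_o <- Phi * (1 - 2.104 * lam + 2.089 * lam^3 - 0.948 * lam^5)
  sig_o <- 1 - (1 - (1 - Phi)^2) *
    (1 - (2 / 3) * lam^2 - 0.163 * lam^3)
  got <- hindrance_coefficients(lam)
  expect_equal(got$H, H_o, tolerance = 1e-12)
  expect_equal(got$sigma_f, sig_o, tolerance = 1e-12)
  expect_error(hindrance_coefficients(1.2), "0, 1")
})

test_that("H decreases and sigma_f increases strictly in lambda", {
  lam <- seq(0, 1, by = 1e-3)
  h <- hindrance_coefficients(lam)
  expect_true(all(diff(h$H) < 0))
  expect_true(all(diff(h$sigma_f) > 0))
  expect_true(all(h$H >= 0 & h$H <= 1))
  expect_true(all(h$sigma_f >= 0 & h$sigma_f <= 1))
})

test_that("wall coefficients anchor at baseline and scale with pore size", {
  sp <- drug_species("doxil", molecular_radius_nm = 45, D_m2_per_s = 6e-12,
                     D_free_m2_per_s = 1.6e-10, k_el_per_s = 1e-5)
  base <- vessel_wall(pore_radius_nm = 200, Lp_m_per_Pa_s = 2.1e-12,
                      Per_m_per_s = c(doxil = 1e-8),
                      sigma_f = c(doxil =
                        hindrance_coefficients(45 / 200)$sigma_f))
  same <- wall_coefficients(200, sp, base)
  expect_equal(same$Lp_m_per_Pa_s, base$Lp_m_per_Pa_s)
  expect_equal(same$Per_m_per_s[["doxil"]], 1e-8)
  dbl <- wall_coefficients(400, sp, base)
  expect_equal(dbl$Lp_m_per_Pa_s / base$Lp_m_per_Pa_s, 4)
  expect_gt(dbl$Per_m_per_s[["doxil"]], base$Per_m_per_s[["doxil"]])
  expect_lt(dbl$sigma_f[["doxil"]], base$sigma_f[["doxil"]])
  # lambda -> 0 limit: reflection vanishes
  wide <- wall_coefficients(100 * 45, sp, base)
  expect_lt(wide$sigma_f[["doxil"]], 0.01)
  expect_warning(clamped <- wall_coefficients(100, sp, base), "clamped")
  expect_equal(clamped$pore_radius_nm, 200)
})

test_that("Starling flux vanishes without gradients and adds both terms", {
  expect_equal(starling_flux(1, 2, 0.5, 0.5, 1, 1000, 1000, 0.3), 0)
  expect_equal(starling_flux(0, 2, 1, 0.2, 1, 1000, 1000, 1), 0)
  expect_equal(starling_flux(1, 2, 1, 0, 0, 1000, 0, 0.5), 2)
  # convection is a source into tissue while p_i < P_V
  expect_gt(starling_flux(0, 1, 1, 1, 1e-3, 2000, 500, 0.2), 0)
})

test_that("transport_rhs matches a hand-written finite-difference oracle", {
  n <- 5
  grid <- radial_grid(2e-3, n)
  species <- list(
    doxil = drug_species("doxil", 45, D_m2_per_s = 6e-12,
                         D_free_m2_per_s = 1.6e-10, k_el_per_s = 5.6e-6,
                         k_int_per_s = 5.6e-5, k_deg_per_s = 5.6e-6,
                         alpha = 1),
    anti_pd1 = drug_species("anti_pd1", 5, D_m2_per_s = 1e-11,
                            k_deg_per_s = 2.8e-6))
  wall <- vessel_wall(200, 2.1e-12, 2000,
                      Per_m_per_s = c(doxil = 1e-8, anti_pd1 = 3e-8),
                      sigma_f = c(doxil = 0.6, anti_pd1 = 0.1))
  set.seed(7)
  fields <- list(cn = runif(n), cf = runif(n), cint = runif(n),
                 cfi = runif(n))
  Sv <- runif(n, 0, 2e4)
  p_i <- runif(n, 0, 1800)
  vel <- list(v_f = numeric(n + 1), v_s = numeric(n + 1), w = numeric(n))
  plasma <- list(C_iv = 0.8, C_iv_i = 0.5)
  got <- transport_rhs(fields, grid, wall, species, vel, plasma, Sv, p_i,
                       bc = "zero_flux")

  # independent oracle: conservative flux differencing written long-hand
  lap <- function(c, D) {
    flux <- numeric(n + 1)
    for (j in 2:n)
      flux[j] <- -D * grid$area[j] * (c[j] - c[j - 1]) / grid$dr
    -(flux[2:(n + 1)] - flux[1:n]) / grid$vol
  }
  s <- 3600
  q_n <- wall$Per_m_per_s[["doxil"]] * s * Sv * (plasma$C_iv - fields$cn) +
    wall$Lp_m_per_Pa_s * s * Sv * (wall$P_V_Pa - p_i) *
      (1 - wall$sigma_f[["doxil"]]) * plasma$C_iv
  o_cn <- lap(fields$cn, 6e-12 * s) + q_n - 5.6e-6 * s * fields$cn
  expect_equal(got$dcn, o_cn, tolerance = 1e-10)
  o_cf <- lap(fields$cf, 1.6e-10 * s) + 5.6e-6 * s * fields$cn -
    5.6e-5 * s * fields$cf
  expect_equal(got$dcf, o_cf, tolerance = 1e-10)
  o_cint <- 5.6e-5 * s * fields$cf - 5.6e-6 * s * fields$cint
  expect_equal(got$dcint, o_cint, tolerance = 1e-10)
  q_i <- wall$Per_m_per_s[["anti_pd1"]] * s * Sv *
    (plasma$C_iv_i - fields$cfi) +
    wall$Lp_m_per_Pa_s * s * Sv * (wall$P_V_Pa - p_i) *
      (1 - wall$sigma_f[["anti_pd1"]]) * plasma$C_iv_i
  o_cfi <- lap(fields$cfi, 1e-11 * s) + q_i - 2.8e-6 * s * fields$cfi
  expect_equal(got$dcfi, o_cfi, tolerance = 1e-10)
})

test_that("transport_rhs fixed points: empty system and uniform field", {
  n <- 8
  grid <- radial_grid(3e-3, n)
  species <- list(
    doxil = drug_species("doxil", 45, D_m2_per_s = 6e-12,
                         D_free_m2_per_s = 1.6e-10),
    anti_pd1 = drug_species("anti_pd1", 5, D_m2_per_s = 1e-11))
  wall <- vessel_wall(200, 2.1e-12, 2000,
                      Per_m_per_s = c(doxil = 1e-8, anti_pd1 = 3e-8),
                      sigma_f = c(doxil = 0.6, anti_pd1 = 0.1))
  vel <- list(v_f = numeric(n + 1), v_s = numeric(n + 1), w = numeric(n))
  zero <- list(cn = numeric(n), cf = numeric(n), cint = numeric(n),
               cfi = numeric(n))
  got <- transport_rhs(zero, grid, wall, species, vel,
                       list(C_iv = 0, C_iv_i = 0), numeric(n), numeric(n),
                       bc = "zero_flux")
  expect_equal(unlist(got[c("dcn", "dcf", "dcint", "dcfi")]),
               rep(0, 4 * n), ignore_attr = TRUE)
  # uniform carrier, no vessels, no release: pure diffusion of a constant
  unif <- list(cn = rep(0.7, n), cf = numeric(n), cint = numeric(n),
               cfi = numeric(n))
  got2 <- transport_rhs(unif, grid, wall, species, vel,
                        list(C_iv = 0, C_iv_i = 0), numeric(n), numeric(n),
                        bc = "zero_flux")
  expect_equal(got2$dcn, rep(0, n))
})

test_that("checkpoint pharmacodynamics saturate and gate correctly", {
  p <- list(a_pd1 = 2, c_half = 0.05, a_ctla4 = 1.5)
  none <- ici_pharmacodynamics(0, 0.0015, 0.01, p, FALSE)
  expect_equal(none$sigma_T8_eff, 0.0015)
  expect_equal(none$m_reg_eff, 0.01)
  sat <- ici_pharmacodynamics(1e9, 0.0015, 0.01, p, FALSE)
  expect_equal(sat$sigma_T8_eff, 0.0015 * 3, tolerance = 1e-6)
  half <- ici_pharmacodynamics(0.05, 0.0015, 0.01, p, FALSE)
  expect_equal(half$sigma_T8_eff, 0.0015 * 2)
  on <- ici_pharmacodynamics(0, 0.0015, 0.01, p, TRUE)
  expect_equal(on$m_reg_eff, 0.025)
})
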