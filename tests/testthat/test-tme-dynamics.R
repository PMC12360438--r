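pop_pars <- function() default_config()$populations

zero_pops <- function(n = 1) {
  p <- lapply(stats::setNames(nm = c("cc", "scc", "icc", "nk", "t8", "t4",
                                     "treg", "m1", "m2")),
              function(x) numeric(n))
  p
}

test_that("cancer dynamics: extinction and anoxia fixed points", {
  p <- pop_pars()
  z <- zero_pops()
  out <- cancer_rhs(z, c_ox = 0.1, c_int = 0, params = p)
  expect_equal(unlist(out[c("dcc", "dscc", "dicc")]), rep(0, 3),
               ignore_attr = TRUE)
  pops <- zero_pops(); pops$cc <- 0.4; pops$scc <- 0.05
  anox <- cancer_rhs(pops, c_ox = 0, c_int = 0, params = p)
  # no oxygen -> no proliferation; only interconversion flows remain
  expect_equal(anox$dcc, p$k_sc * 0.05)
  expect_equal(anox$dscc, -p$k_sc * 0.05)
})

test_that("single population follows the closed-form logistic solution", {
  p <- pop_pars()
  p$k_sc <- 0                              # isolate one compartment
  c_ox <- 0.12
  r <- p$k1 * c_ox
  x0 <- 0.05
  rhs <- function(t, y, parms) {
    pops <- zero_pops(); pops$cc <- y
    list(cancer_rhs(pops, c_ox, 0, p)$dcc)
  }
  tt <- seq(0, 200, by = 5)
  num <- deSolve::ode(x0, tt, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)[, 2]
  closed <- x0 * exp(r * tt) / (1 + x0 * (exp(r * tt) - 1))
  expect_equal(num, closed, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("interconversion flows conserve their compartment sums", {
  p <- pop_pars()
  # pure SCC<->CC and CC->ICC flow: disable growth and kill
  p$k1 <- 0; p$k_drug <- 0
  pops <- zero_pops(); pops$cc <- 0.3; pops$scc <- 0.1; pops$icc <- 0.05
  out <- cancer_rhs(pops, c_ox = 0.1, c_int = 0.5, params = p)
  expect_equal(out$dcc + out$dscc + out$dicc, 0, tolerance = 1e-15)
  # macrophage polarization conserves m1 + m2 exactly
  m1 <- c(0.1, 0.3); m2 <- c(0.2, 0.05)
  flux <- tam_polarization(c(0.02, 0.18), c(0.5, 0.01), m1, m2, p)
  imm_p <- p
  imm_p$sigma_m1 <- 0; imm_p$sigma_m2 <- 0
  imm_p$m_m1 <- 0; imm_p$m_m2 <- 0
  pops2 <- zero_pops(2); pops2$m1 <- m1; pops2$m2 <- m2
  ici0 <- list(sigma_T8_eff = imm_p$sigma_t8, m_reg_eff = imm_p$m_reg)
  out2 <- immune_rhs(pops2, c(0.02, 0.18), ici0, numeric(2),
                     c(0.5, 0.01), imm_p)
  expect_equal(out2$dm1 + out2$dm2, c(0, 0), tolerance = 1e-15)
})

test_that("macrophage polarization follows oxygen and VEGF direction", {
  p <- pop_pars()
  m1 <- 0.2; m2 <- 0.2
  # hypoxic floor with high VEGF: net flux toward M2
  expect_lt(tam_polarization(0.001, 2, m1, m2, p), 0)
  # healthy oxygen, no VEGF: net flux toward M1
  expect_gt(tam_polarization(0.2, 0, m1, m2, p), 0)
})

test_that("immune populations relax to the analytic source/death balance", {
  p <- pop_pars()
  n <- 1
  pops <- zero_pops(n)
  pops$nk <- 0.5; pops$t8 <- 0.01; pops$treg <- 0.4; pops$t4 <- 0.1
  ici0 <- list(sigma_T8_eff = p$sigma_t8, m_reg_eff = p$m_reg)
  rhs <- function(t, y, parms) {
    pops$nk <- y[1]; pops$t8 <- y[2]; pops$t4 <- y[3]; pops$treg <- y[4]
    out <- immune_rhs(pops, p$c_host, ici0, 0, 0, p)
    list(c(out$dnk, out$dt8, out$dt4, out$dtreg))
  }
  end <- deSolve::ode(c(0.5, 0.01, 0.1, 0.4), c(0, 5000), rhs, NULL,
                      rtol = 1e-10, atol = 1e-12)
  steady <- end[nrow(end), -1]
  expect_equal(steady,
               c(p$sigma_nk / p$m_nk, p$sigma_t8 / p$m_t8,
                 p$sigma_t4 / p$m_t4, p$sigma_treg / p$m_reg),
               tolerance = 1e-6, ignore_attr = TRUE)
  # doubling Treg mortality halves the Treg steady state
  ici2 <- list(sigma_T8_eff = p$sigma_t8, m_reg_eff = 2 * p$m_reg)
  pops$treg <- p$sigma_treg / (2 * p$m_reg)
  out <- immune_rhs(pops, p$c_host, ici2, 0, 0, p)
  expect_equal(out$dtreg, 0, tolerance = 1e-12)
})

test_that("anti-PD-1 strictly raises the CD8 source at identical states", {
  p <- pop_pars()
  cfg <- default_config()
  pops <- zero_pops(); pops$t8 <- 0.2
  base <- ici_pharmacodynamics(0, p$sigma_t8, p$m_reg, cfg$ici, FALSE)
  trt <- ici_pharmacodynamics(0.3, p$sigma_t8, p$m_reg, cfg$ici, FALSE)
  d0 <- immune_rhs(pops, 0.1, base, 0, 0, p)$dt8
  d1 <- immune_rhs(pops, 0.1, trt, 0, 0, p)$dt8
  expect_gt(d1, d0)
})

test_that("endothelial dynamics respond to factors as stated", {
  p <- pop_pars()
  sono0 <- list(pr_n = 1, ap_n = 1)
  # VEGF = 0 and Ang2 >> Ang1: proliferation term ~ 0 (death only)
  out <- vascular_rhs(0.4, 0, 0.001, 10, sono0, 0.05, p)
  expect_equal(out$dendo, -p$m_e * 0.4, tolerance = 1e-6)
  # doubling the proliferation factor doubles the proliferation term
  base <- vascular_rhs(0.4, 0.3, 0.2, 0.1, sono0, 0.05, p)
  dbl <- vascular_rhs(0.4, 0.3, 0.2, 0.1, list(pr_n = 2, ap_n = 1),
                      0.05, p)
  prolif <- base$dendo + p$m_e * 0.4
  expect_equal(dbl$dendo + p$m_e * 0.4, 2 * prolif, tolerance = 1e-12)
})

test_that("oxygen balance hits its algebraic fixed point", {
  ox <- default_config()$oxygen
  # no cells: healthy reference everywhere
  expect_equal(oxygen_steady(1, 0, ox), 0.2)
  # one-node reduction: c = c_host * s/(s+u)
  Sv_rel <- 0.4; dens <- 0.9
  s <- ox$k_supply_per_h * Sv_rel
  u <- ox$k_consume_per_h * dens
  expect_equal(oxygen_steady(Sv_rel, dens, ox), 0.2 * s / (s + u),
               tolerance = 1e-10)
  # full dynamics agree at the fixed point (uniform field, no gradients)
  n <- 6
  grid <- radial_grid(2e-3, n)
  c_eq <- rep(0.2 * s / (s + u), n)
  d <- oxygen_rhs(c_eq, rep(Sv_rel, n), rep(dens, n), grid, ox)
  # interior nodes are at equilibrium; boundary feels the host Dirichlet
  expect_equal(d[1:(n - 1)], rep(0, n - 1), tolerance = 1e-10)
  # pure sink decays monotonically
  d2 <- oxygen_rhs(rep(0.1, n), numeric(n), rep(1, n), grid, ox)
  expect_true(all(d2[1:(n - 1)] < 0))
})

test_that("hypoxia percentage is the oxygenation complement", {
  expect_equal(hypoxia_percent(0.2), 0)
  expect_equal(hypoxia_percent(0), 100)
  expect_equal(hypoxia_percent(0.1), 50)
  expect_warning(h <- hypoxia_percent(0.25), "clamped")
  expect_equal(h, 0)
})
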